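test_that("the design matrix codes and centres covariates as specified", {
  d <- group_design(paste0("s", 1:4), engel = c("1a", "1a", "1b", "1b"),
                    age = c(4, 6, 8, 10))
  expect_identical(colnames(d$X), c("intercept", "engel", "age"))
  expect_lt(abs(mean(d$X[, "engel"])), 1e-10)
  expect_lt(abs(mean(d$X[, "age"])), 1e-10)
  expect_equal(d$X[, "engel"], c(1, 1, -1, -1), ignore_attr = TRUE)
  expect_error(group_design("s1", engel = "2a"), "Engel")
})

test_that("identical subjects recover their shared mean", {
  fits <- replicate(8, toy_fit(c(0.3, -0.6), sd = 1e-5), simplify = FALSE)
  des <- group_design(paste0("s", 1:8))
  # vague group prior: the intercept converges to the arithmetic mean
  peb <- fit_peb(fits, des, field = 1:2, beta_prior_var = 1e6)
  expect_lt(max(abs(peb$beta[, "intercept"] - c(0.3, -0.6))), 1e-6)
  # default prior: shrunk toward zero, less so with tighter first levels
  loose <- fit_peb(lapply(1:8, function(i) toy_fit(c(0.3, -0.6), 0.2)),
                   des, field = 1:2)$beta[1, 1]
  tight <- fit_peb(fits, des, field = 1:2)$beta[1, 1]
  expect_lt(abs(loose), 0.3)
  expect_lt(abs(tight - 0.3), abs(loose - 0.3))
})

test_that("the group posterior is exchangeable over subject order", {
  set.seed(5)
  fits <- lapply(1:10, function(i)
    toy_fit(c(0.2, -0.7) + rnorm(2, 0, 0.1), sd = 0.05))
  eng <- rep(c(1, -1), 5)
  des <- group_design(paste0("s", 1:10), engel = eng)
  p1 <- fit_peb(fits, des, field = 1:2)
  ord <- c(7, 3, 10, 1, 5, 9, 2, 8, 6, 4)
  des2 <- group_design(paste0("s", 1:10)[ord], engel = eng[ord])
  p2 <- fit_peb(fits[ord], des2, field = 1:2)
  expect_lt(max(abs(p1$beta - p2$beta)), 1e-8)
  expect_lt(abs(p1$free_energy - p2$free_energy), 1e-6)
})

test_that("adding a constant to age leaves non-intercept effects unchanged", {
  set.seed(6)
  age <- runif(12, 3, 15)
  fits <- lapply(1:12, function(i)
    toy_fit(c(0.2 - 0.01 * age[i], -0.7) + rnorm(2, 0, 0.05), sd = 0.05))
  d1 <- group_design(paste0("s", 1:12), age = age)
  d2 <- group_design(paste0("s", 1:12), age = age + 100)
  p1 <- fit_peb(fits, d1, field = 1:2)
  p2 <- fit_peb(fits, d2, field = 1:2)
  expect_lt(max(abs(p1$beta[, "age"] - p2$beta[, "age"])), 1e-8)
})

test_that("guards reject degenerate groups and designs", {
  fits <- replicate(2, toy_fit(c(0.1, 0.1)), simplify = FALSE)
  des <- group_design(c("a", "b"))
  expect_error(fit_peb(fits, des, field = 1:2), "at least 3")
  fits4 <- replicate(4, toy_fit(c(0.1, 0.1)), simplify = FALSE)
  bad <- group_design(paste0("s", 1:4), age = c(2, 2, 2, 2))
  # constant age column centres to zero: collinear with nothing to fit
  expect_error(fit_peb(fits4, bad, field = 1:2), "rank|collinear")
  expect_error(loo_crossvalidate(fits, des, "engel", field = 1:2),
               "at least 3")
})

test_that("group reduction keeps real effects and prunes null covariates", {
  set.seed(8)
  n <- 16
  eng <- rep(c(1, -1), n / 2)
  retained_real <- retained_null <- 0
  nrep <- 25
  for (r in seq_len(nrep)) {
    fits <- lapply(1:n, function(i)
      toy_fit(c(0.22 + 0.0 * eng[i], -0.73 + 0.25 * eng[i]) +
                rnorm(2, 0, 0.08), sd = 0.05))
    des <- group_design(paste0("s", 1:n), engel = eng)
    rep_ <- group_bmr_bma(fit_peb(fits, des, field = 1:2), 0.95)
    retained_real <- retained_real +
      all(rep_$retained[rep_$parameter %in%
                          c("intercept:p1", "intercept:p2")])
    retained_null <- retained_null + rep_$retained[
      rep_$parameter == "engel:p1"]
  }
  expect_gte(retained_real / nrep, 0.9)   # strong couplings survive
  expect_lt(retained_null / nrep, 0.2)    # null covariate pruned
})

test_that("LOO prediction works and its null p-values are calibrated", {
  set.seed(9)
  # strong effect: high correlation across folds
  n <- 20
  eng <- rep(c(1, -1), n / 2)
  hits <- 0
  for (r in 1:10) {
    fits <- lapply(1:n, function(i)
      toy_fit(c(0.2, -0.7 + 0.5 * eng[i]) + rnorm(2, 0, 0.05), sd = 0.03))
    des <- group_design(paste0("s", 1:n), engel = eng)
    loo <- loo_crossvalidate(fits, des, "engel", field = 1:2)
    hits <- hits + (loo$r > 0.5)
  }
  expect_gte(hits / 10, 0.9)
  # null effect: p approximately uniform across replicate groups
  pvals <- sapply(1:60, function(r) {
    fits <- lapply(1:10, function(i)
      toy_fit(c(0.2, -0.7) + rnorm(2, 0, 0.1), sd = 0.05))
    des <- group_design(paste0("s", 1:10), engel = rep(c(1, -1), 5))
    loo_crossvalidate(fits, des, "engel", field = 1:2)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a copied post session yields no difference effects", {
  set.seed(10)
  pre <- lapply(1:8, function(i)
    toy_fit(c(0.22, -0.73) + rnorm(2, 0, 0.05), sd = 0.04))
  names(pre) <- paste0("s", 1:8)
  pp <- prepost_hierarchy(pre, pre, field = 1:2)
  diffs <- pp$report[pp$report$effect == "pre_minus_post", ]
  expect_true(all(abs(diffs$value) < 0.05))
  expect_true(all(!diffs$retained))
  # commonalities track the session posteriors
  commons <- pp$report[pp$report$effect == "common", ]
  expect_equal(commons$value, c(0.22, -0.73), tolerance = 0.12,
               ignore_attr = TRUE)
})

test_that("single-subject and missing-session cases degrade gracefully", {
  pre <- list(s1 = toy_fit(c(0.2, -0.7)), s2 = toy_fit(c(0.2, -0.7)))
  post <- list(s1 = toy_fit(c(0.0, -0.2)))
  expect_warning(pp <- prepost_hierarchy(pre, post, field = 1:2), "s2")
  expect_true(pp$single_subject)
  expect_identical(pp$subjects, "s1")
  expect_error(suppressWarnings(
    prepost_hierarchy(list(s1 = toy_fit(c(0, 0))),
                      list(s9 = toy_fit(c(0, 0))), field = 1:2)),
    "no subject")
})
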