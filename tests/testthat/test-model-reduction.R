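test_that("identity reduction changes nothing", {
  set.seed(1)
  prior <- list(mean = rep(0, 3), cov = diag(1, 3))
  post <- list(mean = c(0.4, -0.2, 0.1), cov = diag(0.05, 3))
  r <- bayesian_model_reduce(prior, post, prior)
  expect_lt(abs(r$delta_F), 1e-12)
  expect_lt(max(abs(r$posterior$mean - post$mean)), 1e-12)
  expect_lt(max(abs(r$posterior$cov - post$cov)), 1e-12)
})

test_that("reduction equals direct conjugate re-inversion", {
  set.seed(7)
  k <- 4; nobs <- 15
  X <- matrix(rnorm(nobs * k), nobs)
  y <- X %*% c(0.8, -0.5, 0, 0.3) + rnorm(nobs, 0, 0.7)
  m0 <- rep(0, k); C0 <- diag(1, k); s2 <- 0.49
  full <- conjugate_fit(X, y, m0, C0, s2)
  for (off in list(3L, c(2L, 3L), c(1L, 4L))) {
    rC <- C0; rC[cbind(off, off)] <- 1e-8
    direct <- conjugate_fit(X, y, m0, rC, s2)
    bmr <- bayesian_model_reduce(
      list(mean = m0, cov = C0),
      list(mean = full$mean, cov = full$cov),
      list(mean = m0, cov = rC))
    expect_lt(max(abs(bmr$posterior$mean - direct$mean)), 1e-6)
    expect_lt(max(abs(bmr$posterior$cov - direct$cov)), 1e-6)
    expect_lt(abs(bmr$delta_F - (direct$log_evidence - full$log_evidence)),
              1e-6)
  }
})

test_that("switching off a null parameter is favoured (Occam)", {
  prior <- list(mean = rep(0, 2), cov = diag(1, 2))
  post <- list(mean = c(0.9, 0.001), cov = diag(c(0.05, 0.001)))
  rp <- prior; rp$cov[2, 2] <- 1e-8
  r <- bayesian_model_reduce(prior, post, rp)
  expect_gt(r$delta_F, 0)
  # and switching off a clearly non-zero parameter is penalized
  rp2 <- prior; rp2$cov[1, 1] <- 1e-8
  expect_lt(bayesian_model_reduce(prior, post, rp2)$delta_F, 0)
})

test_that("the exhaustive model space has the right size and order", {
  expect_identical(nrow(exhaustive_model_space(0)), 1L)
  expect_identical(nrow(exhaustive_model_space(2)), 4L)
  sp <- exhaustive_model_space(4)
  expect_identical(nrow(sp), 16L)
  expect_true(all(sp[1, ]))            # full model first
  expect_error(exhaustive_model_space(21), "20")
})

test_that("model averaging matches mixture moments", {
  m1 <- list(posterior = list(mean = c(1, 0), cov = diag(0.1, 2)),
             delta_F = 0)
  # single model: identity
  expect_equal(bma(list(m1))$mean, c(1, 0), ignore_attr = TRUE)
  # two identical models: weights half/half, same posterior
  avg2 <- bma(list(m1, m1))
  expect_equal(avg2$model_probs, c(0.5, 0.5))
  expect_equal(avg2$mean, c(1, 0), ignore_attr = TRUE)
  # two-component mixture vs Monte-Carlo moments
  m2 <- list(posterior = list(mean = c(-0.5, 0.8), cov = diag(0.2, 2)),
             delta_F = 0.9)
  avg <- bma(list(m1, m2))
  set.seed(3)
  ndraw <- 1e5
  pick <- sample(1:2, ndraw, replace = TRUE, prob = avg$model_probs)
  mus <- rbind(c(1, 0), c(-0.5, 0.8)); sds <- c(sqrt(0.1), sqrt(0.2))
  draws <- mus[pick, ] + matrix(rnorm(2 * ndraw), ndraw) * sds[pick]
  expect_lt(max(abs(avg$mean - colMeans(draws))), 0.01 * 1.5)
  expect_lt(max(abs(avg$cov - cov(draws)) / (abs(avg$cov) + 0.1)), 0.01 * 2)
  # evidence ordering invariant to adding a constant to all free energies
  shifted <- bma(list(modifyList(m1, list(delta_F = 100)),
                      modifyList(m2, list(delta_F = 100.9))))
  expect_equal(shifted$model_probs, avg$model_probs, tolerance = 1e-10)
})

test_that("model probabilities are coherent over the exhaustive space", {
  csd <- sim_csd(21)
  fit <- invert_dcm(csd)
  red <- reduce_and_average(fit)
  expect_identical(nrow(red$model_space), 16L)   # 2 + 2 couplings
  expect_lt(abs(sum(red$model_probs) - 1), 1e-12)
  expect_identical(red$delta_F[1], 0)            # full model reference
})

test_that("thresholding follows summed model probabilities", {
  csd <- sim_csd(22)
  fit <- invert_dcm(csd)
  red <- reduce_and_average(fit)
  rep9 <- threshold_connections(red, 0.9)
  # Pp equals the sum of probabilities of models with the parameter on
  for (j in seq_along(red$switchable))
    expect_equal(rep9$pp[j], sum(red$model_probs[red$model_space[, j]]))
  expect_identical(rep9$retained, rep9$pp > 0.9)
  # self-connections are decoded to Hz
  expect_true(all(rep9$value[rep9$self] < 0))
  # near-zero threshold retains anything with nonzero probability mass
  rep0 <- threshold_connections(red, 1e-6)
  expect_true(all(rep0$retained[rep0$pp > 1e-6]))
})
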