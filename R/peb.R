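## ---- parametric empirical Bayes over first-level posteriors ----

#' Group design matrix
#'
#' Builds the covariate design for group analysis with columns in the
#' order intercept, Engel class, age.  Engel class 1a is coded +1 and 1b
#' is coded -1; all non-intercept columns are mean-centered.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param engel optional vector of Engel classes (`"1a"`/`"1b"`, or
#'   numeric +1/-1).
#' @param age optional numeric vector of ages (years).
#' @return list of class `group_design` with `X` (matrix), `labels`,
#'   `subject_ids`.
#' @export
group_design <- function(subject_ids, engel = NULL, age = NULL) {
  n <- length(subject_ids)
  X <- matrix(1, n, 1L)
  labels <- "intercept"
  if (!is.null(engel)) {
    if (is.character(engel) || is.factor(engel)) {
      engel <- as.character(engel)
      bad <- setdiff(unique(engel), c("1a", "1b"))
      if (length(bad)) stopf("unknown Engel classes: %s",
                             paste(bad, collapse = ", "))
      engel <- ifelse(engel == "1a", 1, -1)
    }
    if (!all(engel %in% c(-1, 1)))
      stopf("numeric Engel codes must be +1 (class 1a) or -1 (class 1b)")
    X <- cbind(X, engel - mean(engel))
    labels <- c(labels, "engel")
  }
  if (!is.null(age)) {
    X <- cbind(X, age - mean(age))
    labels <- c(labels, "age")
  }
  colnames(X) <- labels
  structure(list(X = X, labels = labels, subject_ids = subject_ids),
            class = "group_design")
}

## core random-effects linear-Gaussian level:
## y_i ~ N(X_i beta, Sigma_i + Gamma), Gamma = diag(base_var) * exp(-gamma);
## beta ~ N(0, beta_prior_var I); gamma ~ N(g0, 1/gprec).  `base_var` sets
## the expected between-subject variance per parameter (one sixteenth of
## the first-level prior variance by convention) and the log-precision
## modulates around it; gamma is optimized on the marginal evidence (a
## one-dimensional Laplace/empirical-Bayes step), beta is then conjugate.
peb_engine <- function(mus, covs, X, base_var = NULL, beta_prior_var = 1,
                       gamma_prior_mean = 0, gamma_prior_prec = 16) {
  n <- length(mus)
  p <- length(mus[[1L]])
  c_ <- ncol(X)
  stopifnot(nrow(X) == n, n >= 1)
  if (is.null(base_var)) base_var <- rep(1 / 16, p)
  base_var <- rep_len(base_var, p)
  y <- unlist(mus, use.names = FALSE)
  ## Z: (n p) x (p c) design for vec(B) with B a p x c coefficient matrix
  Z <- matrix(0, n * p, p * c_)
  for (i in seq_len(n)) for (j in seq_len(c_))
    Z[(i - 1L) * p + seq_len(p), (j - 1L) * p + seq_len(p)] <-
      diag(X[i, j], p)
  Sb0 <- diag(beta_prior_var, p * c_)

  evidence <- function(gamma) {
    G <- base_var * exp(-gamma)
    Vi <- lapply(covs, function(S) S + diag(G, p))
    ## marginal covariance of y: Z Sb0 Z' + blockdiag(Vi)
    M <- Z %*% Sb0 %*% t(Z)
    for (i in seq_len(n)) {
      idx <- (i - 1L) * p + seq_len(p)
      M[idx, idx] <- M[idx, idx] + Vi[[i]]
    }
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    q <- backsolve(ch, y, transpose = TRUE)
    -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2)) -
      0.5 * gamma_prior_prec * (gamma - gamma_prior_mean)^2
  }
  opt <- stats::optimize(evidence, interval = c(-8, 12), maximum = TRUE,
                         tol = 1e-6)
  gamma <- opt$maximum
  G <- base_var * exp(-gamma)
  W <- lapply(covs, function(S) inv_spd(S + diag(G, p)))
  P <- inv_spd(Sb0)
  rhs <- numeric(p * c_)
  for (i in seq_len(n)) {
    idx <- (i - 1L) * p + seq_len(p)
    Zi <- Z[idx, , drop = FALSE]
    P <- P + t(Zi) %*% W[[i]] %*% Zi
    rhs <- rhs + as.numeric(t(Zi) %*% W[[i]] %*% y[idx])
  }
  Sb <- inv_spd(P)
  mb <- as.numeric(Sb %*% rhs)
  ## Laplace correction for the log-precision hyperparameter
  h <- 1e-3
  d2 <- (evidence(gamma + h) - 2 * opt$objective + evidence(gamma - h)) / h^2
  F <- opt$objective +
    0.5 * log(2 * pi / max(-d2, gamma_prior_prec))
  list(beta_mean = mb, beta_cov = Sb, gamma = gamma,
       between_var = base_var * exp(-gamma), free_energy = F,
       beta_prior = list(mean = rep(0, p * c_), cov = Sb0))
}

#' Fit a parametric empirical-Bayes group model
#'
#' Random-effects hierarchy over first-level posteriors:
#' `theta_i ~ N(X_i beta, Gamma)` with `Gamma = exp(-gamma) I` governed by
#' a log-precision hyperparameter, using the first-level posterior means
#' and covariances as data with known uncertainty.  Returns the Gaussian
#' posterior over the group coefficients (one per connection x covariate)
#' and the group free energy.
#'
#' @param fits list of `inversion_result` objects (>= 3) with identical
#'   parameter indexing.
#' @param design a [group_design()].
#' @param field indices of the first-level parameters entering the group
#'   model; default the couplings.
#' @param beta_prior_var prior variance of each group coefficient.
#' @param gamma_prior_mean,gamma_prior_prec Gaussian prior on the
#'   between-subject log precision.
#' @return object of class `peb_result`.
#' @export
fit_peb <- function(fits, design, field = NULL, beta_prior_var = 1,
                    gamma_prior_mean = 0, gamma_prior_prec = 16) {
  stopifnot(inherits(design, "group_design"))
  n <- length(fits)
  if (n < 3L) stopf("PEB needs at least 3 subjects, got %d", n)
  if (nrow(design$X) != n)
    stopf("design has %d rows for %d subjects", nrow(design$X), n)
  qrX <- qr(design$X)
  if (qrX$rank < ncol(design$X))
    stopf("rank-deficient design: collinear columns %s",
          paste(design$labels[-seq_len(qrX$rank)], collapse = ", "))
  nms <- lapply(fits, function(f) names(f$mean))
  if (!all(vapply(nms, identical, logical(1), nms[[1L]])))
    stopf("subjects have mismatched parameter indexing")
  if (is.null(field))
    field <- if (!is.null(fits[[1L]]$n_regions))
      coupling_indices(fits[[1L]]$n_regions) else seq_along(fits[[1L]]$mean)
  mus <- lapply(fits, function(f) unname(f$mean[field]))
  covs <- lapply(fits, function(f) f$cov[field, field, drop = FALSE])
  base_var <- if (!is.null(fits[[1L]]$prior))
    diag(as.matrix(fits[[1L]]$prior$cov))[field] / 16 else NULL
  eng <- peb_engine(mus, covs, design$X, base_var, beta_prior_var,
                    gamma_prior_mean, gamma_prior_prec)
  pnames <- nms[[1L]][field]
  cnames <- design$labels
  bnames <- as.vector(outer(pnames, cnames,
                            function(p, c) paste0(c, ":", p)))
  structure(list(
    beta = matrix(eng$beta_mean, length(field), length(cnames),
                  dimnames = list(pnames, cnames)),
    mean = stats::setNames(eng$beta_mean, bnames),
    cov = eng$beta_cov, gamma = eng$gamma,
    between_var = eng$between_var,
    free_energy = eng$free_energy,
    prior = list(mean = stats::setNames(eng$beta_prior$mean, bnames),
                 cov = eng$beta_prior$cov, names = bnames),
    design = design, field = field, param_names = pnames,
    n_subjects = n), class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("<peb_result> %d subjects, %d parameters x %d covariates, F = %.2f\n",
              x$n_subjects, nrow(x$beta), ncol(x$beta), x$free_energy))
  print(round(x$beta, 4))
  invisible(x)
}

#' Exhaustive reduction and averaging of group effects
#'
#' Applies exhaustive on/off Bayesian model reduction and averaging over
#' the group coefficients and thresholds at the group posterior
#' probability (default 0.95).
#'
#' @param peb a `peb_result`.
#' @param pp_threshold retention threshold; default 0.95.
#' @return a `connection_report` data frame (parameter, value, pp,
#'   retained).
#' @export
group_bmr_bma <- function(peb, pp_threshold = 0.95) {
  stopifnot(inherits(peb, "peb_result"))
  pseudo_fit <- list(mean = peb$mean, cov = peb$cov, prior = peb$prior,
                     n_regions = NULL, labels = NULL)
  red <- reduce_and_average(pseudo_fit, switchable = seq_along(peb$mean))
  threshold_connections(red, pp_threshold)
}

#' Leave-one-out predictive validation of a covariate effect
#'
#' For each subject, fits the PEB model on the remaining subjects and
#' predicts the left-out subject's covariate value from its first-level
#' parameters under the group model (posterior mean of the covariate
#' given the subject's first-level posterior mean).  Predictions are
#' correlated with the true covariate across folds; the one-tailed p value
#' uses `df = n - 2`.
#'
#' @param fits list of `inversion_result` objects.
#' @param design a [group_design()]; must contain `covariate`.
#' @param covariate name of the design column to predict.
#' @param field first-level parameter indices (default couplings).
#' @param ... forwarded to [fit_peb()].
#' @return list with `r`, `p`, `df`, `predictions`, `observed`.
#' @export
loo_crossvalidate <- function(fits, design, covariate = "engel",
                              field = NULL, ...) {
  n <- length(fits)
  if (n < 3L) stopf("LOO cross-validation needs at least 3 subjects")
  ci <- match(covariate, design$labels)
  if (is.na(ci)) stopf("design has no covariate '%s'", covariate)
  if (is.null(field))
    field <- if (!is.null(fits[[1L]]$n_regions))
      coupling_indices(fits[[1L]]$n_regions) else seq_along(fits[[1L]]$mean)
  Xfull <- design$X
  z_obs <- Xfull[, ci]
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    Xt <- Xfull[train, , drop = FALSE]
    ## re-center non-intercept columns within the training set
    shifts <- numeric(ncol(Xt))
    for (j in seq_len(ncol(Xt))[-1L]) {
      shifts[j] <- mean(Xt[, j])
      Xt[, j] <- Xt[, j] - shifts[j]
    }
    dtr <- structure(list(X = Xt, labels = design$labels,
                          subject_ids = design$subject_ids[train]),
                     class = "group_design")
    peb <- fit_peb(fits[train], dtr, field = field, ...)
    B <- peb$beta
    p <- length(field)
    Wi <- inv_spd(fits[[i]]$cov[field, field, drop = FALSE] +
                    diag(peb$between_var, p))
    xi <- Xfull[i, ] - shifts
    base <- as.numeric(B[, -ci, drop = FALSE] %*% xi[-ci])
    b <- B[, ci]
    resid <- unname(fits[[i]]$mean[field]) - base
    ## Gaussian prior on the unknown covariate from the training spread
    v0 <- max(stats::var(Xt[, ci]), 1e-8)
    prec <- as.numeric(t(b) %*% Wi %*% b) + 1 / v0
    preds[i] <- as.numeric(t(b) %*% Wi %*% resid) / prec + 0 # prior mean 0
  }
  r <- stats::cor(preds, z_obs)
  df <- n - 2L
  tval <- r * sqrt(df / max(1 - r^2, 1e-12))
  p <- stats::pt(tval, df, lower.tail = FALSE)
  list(r = r, p = p, df = df, predictions = preds, observed = z_obs)
}

#' Three-level pre/post-operative hierarchy
#'
#' Level 1 is the session (separately inverted pre- and post-operative
#' DCMs, no reduction); level 2 is one PEB per subject over its two
#' sessions with design columns commonality `[1, 1]` and difference
#' `[0.5, -0.5]` (so the difference coefficient is pre minus post);
#' level 3 is a PEB across subjects over the level-2 coefficients,
#' followed by exhaustive reduction and averaging thresholded at the
#' given posterior probability (default 0.9).
#'
#' Subjects missing a session (for example an obliterated post-operative
#' seizure-onset zone with no extractable signal) are listed and skipped
#' with a warning.
#'
#' @param pre_fits,post_fits named lists of `inversion_result` objects;
#'   names identify subjects.
#' @param field first-level parameter indices (default couplings).
#' @param pp_threshold level-3 retention threshold.
#' @return list of class `prepost_result`: `report` (thresholded level-3
#'   effects with `effect` commonality/difference), `level3` (PEB),
#'   `level2` (per-subject PEBs), `subjects`, `single_subject` flag.
#' @export
prepost_hierarchy <- function(pre_fits, post_fits, field = NULL,
                              pp_threshold = 0.9) {
  subjects <- intersect(names(pre_fits), names(post_fits))
  missing <- setdiff(union(names(pre_fits), names(post_fits)), subjects)
  if (length(missing))
    warnf("skipping subjects without both sessions: %s",
          paste(missing, collapse = ", "))
  if (length(subjects) == 0L) stopf("no subject has both sessions")
  f1 <- pre_fits[[subjects[1L]]]
  if (is.null(field))
    field <- if (!is.null(f1$n_regions))
      coupling_indices(f1$n_regions) else seq_along(f1$mean)
  p <- length(field)
  X2 <- cbind(common = c(1, 1), pre_minus_post = c(0.5, -0.5))

  level2 <- lapply(subjects, function(s) {
    mus <- list(unname(pre_fits[[s]]$mean[field]),
                unname(post_fits[[s]]$mean[field]))
    covs <- list(pre_fits[[s]]$cov[field, field, drop = FALSE],
                 post_fits[[s]]$cov[field, field, drop = FALSE])
    base2 <- if (!is.null(pre_fits[[s]]$prior))
      diag(as.matrix(pre_fits[[s]]$prior$cov))[field] / 16 else NULL
    peb_engine(mus, covs, X2, base2)
  })
  names(level2) <- subjects
  pnames <- names(f1$mean)[field]
  bnames <- as.vector(outer(pnames, colnames(X2),
                            function(a, b) paste0(b, ":", a)))

  if (length(subjects) == 1L) {
    l2 <- level2[[1L]]
    report <- data.frame(parameter = bnames, value = l2$beta_mean,
                         pp = NA_real_, retained = NA)
    return(structure(list(report = report, level3 = NULL, level2 = level2,
                          subjects = subjects, single_subject = TRUE),
                     class = "prepost_result"))
  }

  mus3 <- lapply(level2, `[[`, "beta_mean")
  covs3 <- lapply(level2, `[[`, "beta_cov")
  X3 <- matrix(1, length(subjects), 1L, dimnames = list(NULL, "intercept"))
  l3 <- peb_engine(mus3, covs3, X3)
  pseudo_fit <- list(
    mean = stats::setNames(l3$beta_mean, bnames),
    cov = l3$beta_cov,
    prior = list(mean = stats::setNames(l3$beta_prior$mean, bnames),
                 cov = l3$beta_prior$cov, names = bnames),
    n_regions = NULL, labels = NULL)
  red <- reduce_and_average(pseudo_fit, switchable = seq_along(bnames))
  report <- threshold_connections(red, pp_threshold)
  report$effect <- rep(c("common", "pre_minus_post"), each = p)
  report$connection <- rep(pnames, times = 2L)
  structure(list(report = report, level3 = l3, level2 = level2,
                 subjects = subjects, single_subject = FALSE),
            class = "prepost_result")
}
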