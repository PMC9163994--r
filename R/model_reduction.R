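## ---- Bayesian model reduction, averaging, and thresholding ----

## prior variance encoding a switched-off parameter; exactly zero would
## break the precision algebra
.off_variance <- 1e-8

#' Analytic Bayesian model reduction
#'
#' Computes the posterior and log-evidence change of a model with a
#' reduced prior from the full model's prior and posterior, without
#' refitting.  In precision form: the reduced posterior precision is
#' `full posterior precision + reduced prior precision - full prior
#' precision`, with the corresponding closed-form change in log evidence.
#'
#' @param prior,posterior,reduced_prior lists with `mean` and `cov`
#'   (dimension-consistent Gaussians).
#' @return list with `posterior` (mean, cov) and `delta_F` (nats, relative
#'   to the full model).
#' @export
bayesian_model_reduce <- function(prior, posterior, reduced_prior) {
  pE <- as.numeric(prior$mean);    pC <- as.matrix(prior$cov)
  qE <- as.numeric(posterior$mean); qC <- as.matrix(posterior$cov)
  rE <- as.numeric(reduced_prior$mean); rC <- as.matrix(reduced_prior$cov)
  k <- length(pE)
  if (length(qE) != k || length(rE) != k ||
      any(dim(pC) != k) || any(dim(qC) != k) || any(dim(rC) != k))
    stopf("dimension mismatch between prior, posterior and reduced prior")
  pP <- inv_spd(pC); qP <- inv_spd(qC); rP <- inv_spd(rC)
  sP <- qP + rP - pP
  ev <- eigen((sP + t(sP)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stopf("invalid reduction: reduced posterior precision not positive definite")
  sC <- inv_spd(sP)
  sE <- as.numeric(sC %*% (qP %*% qE + rP %*% rE - pP %*% pE))
  dF <- 0.5 * (logdet(rP) + logdet(qP) - logdet(pP) - logdet(sP)) -
    0.5 * (sum(qE * (qP %*% qE)) + sum(rE * (rP %*% rE)) -
             sum(pE * (pP %*% pE)) - sum(sE * (sP %*% sE)))
  list(posterior = list(mean = stats::setNames(sE, names(posterior$mean)),
                        cov = sC),
       delta_F = dF)
}

#' Exhaustive on/off model space
#'
#' All `2^k` on/off combinations of `k` switchable parameters, in a
#' deterministic order with the full (all-on) model first.
#'
#' @param k number of switchable parameters (at most 20).
#' @return logical matrix (models x parameters); `TRUE` means on.
#' @export
exhaustive_model_space <- function(k) {
  if (k > 20L) stopf("refusing an exhaustive space with k = %d > 20", k)
  if (k == 0L) return(matrix(logical(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Bayesian model averaging
#'
#' Evidence-weighted average over reduced models: model probabilities are
#' the softmax of the free energies; the averaged posterior is the
#' moment-matched Gaussian of the mixture (probability-weighted means;
#' weighted within-model plus between-model covariance).
#'
#' @param models list of results from [bayesian_model_reduce()] (each with
#'   `posterior` and `delta_F`).
#' @return list with `mean`, `cov`, `model_probs`.
#' @export
bma <- function(models) {
  stopifnot(length(models) >= 1)
  dF <- vapply(models, `[[`, numeric(1), "delta_F")
  if (all(!is.finite(dF))) stopf("all model evidences are -Inf")
  w <- exp(dF - max(dF[is.finite(dF)]))
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  mus <- lapply(models, function(m) as.numeric(m$posterior$mean))
  covs <- lapply(models, function(m) as.matrix(m$posterior$cov))
  mu <- Reduce(`+`, Map(`*`, mus, w))
  cv <- Reduce(`+`, Map(function(m, C, wk)
    wk * (C + tcrossprod(m - mu)), mus, covs, w))
  list(mean = stats::setNames(mu, names(models[[1L]]$posterior$mean)),
       cov = cv, model_probs = w)
}

#' Exhaustive reduction and averaging of an inversion
#'
#' Builds the exhaustive on/off model space over the switchable parameters
#' (by default all couplings: off-diagonals and self-connections), reduces
#' the full posterior analytically for every model, and averages.
#'
#' @param fit an `inversion_result` (or any list with `mean`, `cov`,
#'   `prior`).
#' @param switchable indices (into the parameter vector) of switchable
#'   parameters; default [coupling_indices()] when `fit` carries
#'   `n_regions`, otherwise all parameters.
#' @return list of class `bmr_bma`: `bma` (averaged posterior),
#'   `model_space`, `delta_F` per model, `model_probs`, `switchable`.
#' @export
reduce_and_average <- function(fit, switchable = NULL) {
  if (is.null(switchable))
    switchable <- if (!is.null(fit$n_regions))
      coupling_indices(fit$n_regions) else seq_along(fit$mean)
  prior <- fit$prior
  posterior <- list(mean = fit$mean, cov = fit$cov)
  space <- exhaustive_model_space(length(switchable))
  models <- lapply(seq_len(nrow(space)), function(m) {
    off <- switchable[!space[m, ]]
    if (length(off) == 0L)                 # full model: exact reference
      return(list(posterior = posterior, delta_F = 0))
    rp <- prior
    rp$mean[off] <- 0
    rp$cov[off, ] <- 0; rp$cov[, off] <- 0
    rp$cov[cbind(off, off)] <- .off_variance
    bayesian_model_reduce(prior, posterior, rp)
  })
  avg <- bma(models)
  structure(list(bma = avg, model_space = space,
                 delta_F = vapply(models, `[[`, numeric(1), "delta_F"),
                 model_probs = avg$model_probs, switchable = switchable,
                 labels = fit$labels, n_regions = fit$n_regions),
            class = "bmr_bma")
}

#' Threshold connections on posterior probability
#'
#' Per switchable parameter, the posterior probability of being "on" is
#' the summed probability of the models in which it is on; a connection is
#' retained when that probability exceeds the threshold.  Values come from
#' the model-averaged posterior; self-connections are decoded from the log
#' scaling to Hz via `-0.5 * exp(value)`.
#'
#' @param red a `bmr_bma` from [reduce_and_average()].
#' @param pp_threshold retention threshold in (0, 1); default 0.9.
#' @return data frame of class `connection_report`: parameter, source,
#'   target, self, value (Hz), pp, retained, threshold.
#' @export
threshold_connections <- function(red, pp_threshold = 0.9) {
  assert_prob(pp_threshold, "pp_threshold")
  sw <- red$switchable
  pp <- vapply(seq_along(sw), function(j)
    sum(red$model_probs[red$model_space[, j]]), numeric(1))
  nm <- names(red$bma$mean)[sw]
  val <- unname(red$bma$mean[sw])
  n <- red$n_regions
  src <- tgt <- rep(NA_character_, length(sw))
  selfs <- rep(FALSE, length(sw))
  if (!is.null(n)) {
    ce_names <- param_names(n, red$labels)
    for (j in seq_along(sw)) {
      idx <- sw[j]
      if (idx <= n * (n - 1L)) {
        m <- regmatches(ce_names[idx],
                        regexec("^a\\[(.+)<-(.+)\\]$", ce_names[idx]))[[1L]]
        tgt[j] <- m[2L]; src[j] <- m[3L]
      } else if (idx <= n * n) {
        r <- idx - n * (n - 1L)
        src[j] <- tgt[j] <- red$labels[r]
        selfs[j] <- TRUE
        val[j] <- -0.5 * exp(val[j])          # decode log scaling to Hz
      }
    }
  }
  out <- data.frame(parameter = nm, source = src, target = tgt,
                    self = selfs, value = val, pp = pp,
                    retained = pp > pp_threshold,
                    threshold = pp_threshold)
  class(out) <- c("connection_report", "data.frame")
  out
}
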