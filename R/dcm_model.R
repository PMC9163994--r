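## ---- cross-spectral DCM generative model ----

## parameter-vector layout for n regions:
##   a[target<-source] off-diagonals (column-major), a_self_log, fluct_amp_log,
##   fluct_exp_dev, noise_amp_log, noise_exp_dev, hemo_scale_log
## couplings in Hz; self-decay decodes as -0.5 * exp(a_self_log) Hz.

param_names <- function(n, labels = paste0("R", seq_len(n))) {
  off <- c()
  for (j in seq_len(n)) for (i in seq_len(n))
    if (i != j) off <- c(off, sprintf("a[%s<-%s]", labels[i], labels[j]))
  c(off,
    sprintf("a_self[%s]", labels),
    sprintf("fluct_amp[%s]", labels),
    sprintf("fluct_exp[%s]", labels),
    sprintf("noise_amp[%s]", labels),
    sprintf("noise_exp[%s]", labels),
    sprintf("hemo[%s]", labels))
}

## decode a named parameter vector into structured pieces
decode_params <- function(theta, n) {
  n_off <- n * (n - 1L)
  off <- theta[seq_len(n_off)]
  A <- matrix(0, n, n)
  k <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) if (i != j) {
    k <- k + 1L; A[i, j] <- off[k]
  }
  idx <- n_off
  take <- function() { out <- theta[idx + seq_len(n)]; idx <<- idx + n; out }
  a_self_log <- take()
  diag(A) <- -0.5 * exp(a_self_log)
  list(A = A, a_self_log = a_self_log,
       fluct_amp_log = take(), fluct_exp_dev = take(),
       noise_amp_log = take(), noise_exp_dev = take(),
       hemo_scale_log = take())
}

## indices of the coupling block (off-diagonals then self log-scales)
coupling_indices <- function(n) seq_len(n * (n - 1L) + n)

#' Gaussian prior over DCM parameters
#'
#' Shrinkage priors for the spectral DCM: zero-mean with variances 1/64 on
#' off-diagonal couplings, log-amplitudes and exponent deviations, and
#' 1/256 on self-connection log-scales and haemodynamic log-gains.
#'
#' @param n_regions number of regions.
#' @param labels region labels.
#' @param v_offdiag,v_self,v_spectral,v_hemo prior variances per block.
#' @return list of class `gaussian_prior` with `mean`, `cov`, `names`.
#' @export
dcm_priors <- function(n_regions, labels = paste0("R", seq_len(n_regions)),
                       v_offdiag = 1 / 64, v_self = 1 / 256,
                       v_spectral = 1 / 64, v_hemo = 1 / 256) {
  n <- n_regions
  nm <- param_names(n, labels)
  v <- c(rep(v_offdiag, n * (n - 1L)), rep(v_self, n),
         rep(v_spectral, 4L * n), rep(v_hemo, n))
  structure(list(mean = stats::setNames(rep(0, length(nm)), nm),
                 cov = diag(v, length(nm)), names = nm),
            class = "gaussian_prior")
}

## base amplitudes anchoring the power-law spectra at parameter zero;
## their ratio sets the model's assumed signal-to-noise operating point
.fv0 <- 1
.ge0 <- 1 / 256

## fast internal evaluation of the generative model: returns the stacked
## residual-space vector (real diagonals, then Re/Im upper off-diagonals,
## frequency-major) without container validation; h0 is the precomputed
## haemodynamic frequency response on the grid
csd_model_vector <- function(theta, freq_hz, n, h0) {
  pp <- decode_params(theta, n)
  A <- pp$A
  if (n == 2L) {
    tr <- A[1, 1] + A[2, 2]
    dt_ <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    disc <- tr * tr / 4 - dt_
    re_max <- if (disc >= 0) tr / 2 + sqrt(disc) else tr / 2
    if (re_max >= 0) stopf("unstable A matrix")
    z <- 2i * pi * freq_hz
    gv1 <- .fv0 * exp(pp$fluct_amp_log[1]) * freq_hz^(-(1 + pp$fluct_exp_dev[1]))
    gv2 <- .fv0 * exp(pp$fluct_amp_log[2]) * freq_hz^(-(1 + pp$fluct_exp_dev[2]))
    ge1 <- .ge0 * exp(pp$noise_amp_log[1]) * freq_hz^(-(1 + pp$noise_exp_dev[1]))
    ge2 <- .ge0 * exp(pp$noise_amp_log[2]) * freq_hz^(-(1 + pp$noise_exp_dev[2]))
    h1 <- h0 * exp(pp$hemo_scale_log[1]); h2 <- h0 * exp(pp$hemo_scale_log[2])
    det <- (z - A[1, 1]) * (z - A[2, 2]) - A[1, 2] * A[2, 1]
    H11 <- h1 * (z - A[2, 2]) / det; H12 <- h1 * A[1, 2] / det
    H21 <- h2 * A[2, 1] / det;       H22 <- h2 * (z - A[1, 1]) / det
    g11 <- Mod(H11)^2 * gv1 + Mod(H12)^2 * gv2 + ge1
    g22 <- Mod(H21)^2 * gv1 + Mod(H22)^2 * gv2 + ge2
    g12 <- H11 * Conj(H21) * gv1 + H12 * Conj(H22) * gv2
    return(c(g11, g22, Re(g12), Im(g12)))
  }
  csd_to_vector(predict_csd(theta, freq_hz, n))
}

#' Predicted cross-spectral density
#'
#' Evaluates the generative model
#' `G_y(f) = H(f) G_v(f) H(f)^H + G_e(f)` with
#' `H(f) = diag(h_r(f) exp(hemo_r)) (2 pi i f I - A)^-1`, where `h_r` is
#' the balloon-model frequency response, and `G_v`, `G_e` are diagonal
#' power-law spectra with exponent `1 + dev`.
#'
#' @param theta named parameter vector (see [dcm_priors()] for layout).
#' @param freq_hz frequency grid (Hz).
#' @param n_regions number of regions.
#' @param constants haemodynamic constants.
#' @param labels region labels.
#' @return a [cross_spectral_density()].
#' @export
predict_csd <- function(theta, freq_hz, n_regions,
                        constants = hemo_constants(),
                        labels = paste0("R", seq_len(n_regions))) {
  n <- n_regions
  pp <- decode_params(theta, n)
  ev <- eigen(pp$A, only.values = TRUE)$values
  if (!all(Re(ev) < 0))
    stopf("unstable A matrix (eigenvalue real parts %s)",
          paste(signif(Re(ev), 3), collapse = ", "))
  h0 <- hemodynamic_transfer(freq_hz, constants = constants)
  gv <- vapply(seq_len(n), function(r)
    .fv0 * exp(pp$fluct_amp_log[r]) * freq_hz^(-(1 + pp$fluct_exp_dev[r])),
    numeric(length(freq_hz)))
  ge <- vapply(seq_len(n), function(r)
    .ge0 * exp(pp$noise_amp_log[r]) * freq_hz^(-(1 + pp$noise_exp_dev[r])),
    numeric(length(freq_hz)))
  hr <- lapply(seq_len(n), function(r) h0 * exp(pp$hemo_scale_log[r]))
  nf <- length(freq_hz)
  S <- array(complex(real = 0), dim = c(n, n, nf))
  z <- 2i * pi * freq_hz
  if (n == 2L) {
    ## closed-form 2x2 resolvent, vectorized over frequency
    a11 <- pp$A[1, 1]; a12 <- pp$A[1, 2]; a21 <- pp$A[2, 1]; a22 <- pp$A[2, 2]
    det <- (z - a11) * (z - a22) - a12 * a21
    T11 <- (z - a22) / det; T12 <- a12 / det
    T21 <- a21 / det;       T22 <- (z - a11) / det
    H11 <- hr[[1]] * T11; H12 <- hr[[1]] * T12
    H21 <- hr[[2]] * T21; H22 <- hr[[2]] * T22
    g11 <- Mod(H11)^2 * gv[, 1] + Mod(H12)^2 * gv[, 2] + ge[, 1]
    g22 <- Mod(H21)^2 * gv[, 1] + Mod(H22)^2 * gv[, 2] + ge[, 2]
    g12 <- H11 * Conj(H21) * gv[, 1] + H12 * Conj(H22) * gv[, 2]
    S[1, 1, ] <- g11; S[2, 2, ] <- g22
    S[1, 2, ] <- g12; S[2, 1, ] <- Conj(g12)
  } else {
    for (k in seq_len(nf)) {
      Tk <- solve(diag(z[k], n) - pp$A)
      Hk <- diag(vapply(hr, `[`, complex(1), k), n) %*% Tk
      Sk <- Hk %*% diag(gv[k, ] + 0i, n) %*% Conj(t(Hk)) + diag(ge[k, ], n)
      S[, , k] <- (Sk + Conj(t(Sk))) / 2
    }
  }
  cross_spectral_density(freq_hz, S, labels = labels)
}

## stack a CSD into the real residual vector used by the inverter:
## unique upper-triangular entries across frequencies, real diagonals,
## real and imaginary parts of off-diagonals
csd_to_vector <- function(csd) {
  n <- dim(csd$matrices)[1]
  nf <- dim(csd$matrices)[3]
  out <- c()
  for (i in seq_len(n)) out <- c(out, Re(csd$matrices[i, i, ]))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out <- c(out, Re(csd$matrices[i, j, ]), Im(csd$matrices[i, j, ]))
  }
  out
}

#' Posterior probability of a parameter
#'
#' For coupling parameters, the posterior probability that the parameter
#' shares the sign of its posterior mean (one minus the Gaussian tail
#' across zero); for log-scale parameters, the probability of exceeding
#' the prior mean in the direction of the posterior mean.
#'
#' @param mean,sd posterior marginal mean and standard deviation.
#' @param prior_mean reference value (0 for couplings; the prior mean for
#'   log-scale parameters).
#' @return probability in `[0.5, 1]`.
#' @export
parameter_posterior_prob <- function(mean, sd, prior_mean = 0) {
  if (any(sd < 0)) stopf("negative posterior SD")
  out <- numeric(length(mean))
  for (k in seq_along(mean)) {
    if (sd[k] == 0) {
      warnf("degenerate posterior (zero SD); returning probability 1")
      out[k] <- 1
    } else {
      out[k] <- stats::pnorm(abs(mean[k] - prior_mean[min(k, length(prior_mean))]) / sd[k])
    }
  }
  out
}
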