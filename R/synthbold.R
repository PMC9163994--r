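## ---- ground-truth networks and synthetic resting-state BOLD ----

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

#' Ground-truth effective-connectivity network
#'
#' Defines the directed two-(or more-)node network from which synthetic
#' resting-state BOLD is generated: off-diagonal couplings in Hz, log-scaled
#' self-connections (effective self-decay `-0.5 * exp(a_self_log)` Hz),
#' power-law endogenous fluctuation and observation-noise spectra, and a
#' per-region haemodynamic gain.
#'
#' @param a_offdiag square matrix of directed couplings in Hz; entry
#'   `[i, j]` is the influence of region `j` on region `i`; the diagonal is
#'   ignored (self-connections come from `a_self_log`).
#' @param a_self_log per-region unitless log-scale of the self-connection.
#' @param fluct_amp,fluct_exp amplitude ((signal units)^2 s) and exponent of
#'   the power-law spectrum `amp * f^(-exp)` of endogenous neural
#'   fluctuations, per region.
#' @param noise_amp,noise_exp same for additive observation noise at the
#'   sampled time points.
#' @param hemo_scale per-region dimensionless gain on the haemodynamic
#'   response.
#' @param labels region labels.
#' @return object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(a_offdiag, a_self_log = 0,
                                 fluct_amp = 1e-5, fluct_exp = 1,
                                 noise_amp = 2e-7, noise_exp = 0.5,
                                 hemo_scale = 1, labels = NULL) {
  a_offdiag <- as.matrix(a_offdiag)
  n <- nrow(a_offdiag)
  stopifnot(ncol(a_offdiag) == n)
  rep_n <- function(x) rep_len(x, n)
  a_self_log <- rep_n(a_self_log)
  fluct_amp <- rep_n(fluct_amp); fluct_exp <- rep_n(fluct_exp)
  noise_amp <- rep_n(noise_amp); noise_exp <- rep_n(noise_exp)
  hemo_scale <- rep_n(hemo_scale)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  if (any(fluct_amp <= 0) || any(noise_amp < 0))
    stopf("spectral amplitudes must be positive")
  if (any(fluct_exp < 0 | fluct_exp > 2) || any(noise_exp < 0 | noise_exp > 2))
    stopf("power-law exponents must lie in [0, 2]")
  net <- structure(
    list(n_regions = n, a_offdiag = a_offdiag, a_self_log = a_self_log,
         fluct_amp = fluct_amp, fluct_exp = fluct_exp,
         noise_amp = noise_amp, noise_exp = noise_exp,
         hemo_scale = hemo_scale, labels = labels),
    class = "ground_truth_network")
  A <- full_coupling_matrix(net)
  ev <- eigen(A, only.values = TRUE)$values
  if (!all(Re(ev) < 0))
    stopf("unstable network: eigenvalue real parts %s (all must be < 0)",
          paste(signif(Re(ev), 3), collapse = ", "))
  net
}

#' Full coupling matrix in Hz
#'
#' Off-diagonal couplings with the decoded self-decays
#' `-0.5 * exp(a_self_log)` on the diagonal.
#'
#' @param net a [ground_truth_network()].
#' @return square numeric matrix (Hz).
#' @export
full_coupling_matrix <- function(net) {
  A <- net$a_offdiag
  diag(A) <- -0.5 * exp(net$a_self_log)
  A
}

#' Default seizure-network ground truth
#'
#' Two regions labelled SOZ and pZ with the couplings reported as
#' pre-operative cohort means: excitatory SOZ to pZ at +0.22 Hz and
#' inhibitory pZ to SOZ at -0.73 Hz, self log-scales 0 (decay -0.5 Hz).
#'
#' @param a_soz_to_pz,a_pz_to_soz couplings in Hz.
#' @param ... passed to [ground_truth_network()].
#' @export
soz_network <- function(a_soz_to_pz = 0.22, a_pz_to_soz = -0.73, ...) {
  A <- matrix(0, 2, 2)
  A[2, 1] <- a_soz_to_pz                    # SOZ (1) drives pZ (2)
  A[1, 2] <- a_pz_to_soz                    # pZ inhibits SOZ
  ground_truth_network(A, labels = c("SOZ", "pZ"), ...)
}

#' Acquisition specification
#'
#' @param tr_seconds repetition time (s).
#' @param volumes_per_run number of volumes per run.
#' @param n_runs number of runs.
#' @param seed RNG seed recorded in all outputs.
#' @param run_offset_sd standard deviation (signal units) of the random
#'   per-run intensity offset injected to exercise concatenation
#'   correction; set 0 to disable.
#' @export
acquisition_spec <- function(tr_seconds = 2, volumes_per_run = 300,
                             n_runs = 2, seed = 1, run_offset_sd = 1) {
  stopifnot(tr_seconds > 0, volumes_per_run >= 16, n_runs >= 1,
            run_offset_sd >= 0)
  structure(list(tr_seconds = tr_seconds, volumes_per_run = volumes_per_run,
                 n_runs = n_runs, seed = as.integer(seed),
                 run_offset_sd = run_offset_sd),
            class = "acquisition_spec")
}

## real series of length n (step dt) with two-sided power spectral density
## amp * f^(-exponent), floored below 1/(n*dt); spectral synthesis by
## frequency-domain filtering of white noise.  amp = 0 returns zeros.
powerlaw_series <- function(n, dt, amp, exponent) {
  if (amp == 0) return(numeric(n))
  w <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / (n * dt)
  f <- pmax(f, 1 / (n * dt))               # low-frequency floor
  s <- amp * f^(-exponent)
  Re(stats::fft(w * sqrt(s / dt), inverse = TRUE)) / n
}

#' Simulate neural dynamics with known directed coupling
#'
#' Euler-Maruyama integration of `dx/dt = A x + v`, where `A` is the full
#' coupling matrix of the network and `v` is, per region, an endogenous
#' fluctuation with power-law spectrum `fluct_amp * f^(-fluct_exp)`
#' generated by spectral synthesis.  An initial burn-in is discarded.
#'
#' @param net a [ground_truth_network()]; must be stable.
#' @param duration length of the returned series (s).
#' @param dt integration step (s), at most 0.2.
#' @param burn_in discarded initial transient (s).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return list with `states` (regions x time), `fluct` (the drive),
#'   `time`, `dt`.
#' @export
simulate_neural <- function(net, duration, dt = 0.1, burn_in = 60,
                            seed = NULL) {
  stopifnot(inherits(net, "ground_truth_network"), dt <= 0.2, dt > 0,
            duration > 0)
  A <- full_coupling_matrix(net)
  if (!is_stable(A))
    stopf("unstable network: cannot simulate (eigenvalue real parts %s)",
          paste(signif(Re(eigen(A, only.values = TRUE)$values), 3),
                collapse = ", "))
  n <- net$n_regions
  nt <- ceiling((duration + burn_in) / dt)
  with_seed(seed, {
    v <- matrix(0, n, nt)
    for (r in seq_len(n))
      v[r, ] <- powerlaw_series(nt, dt, net$fluct_amp[r], net$fluct_exp[r])
    x <- matrix(0, n, nt)
    Ad <- diag(n) + A * dt
    for (t in seq_len(nt - 1L))
      x[, t + 1L] <- Ad %*% x[, t] + v[, t] * dt
    keep <- (nt - ceiling(duration / dt) + 1L):nt
    list(states = x[, keep, drop = FALSE], fluct = v[, keep, drop = FALSE],
         time = (seq_along(keep) - 1L) * dt, dt = dt)
  })
}

#' Simulate BOLD from a ground-truth network
#'
#' Neural simulation followed by balloon-model haemodynamic convolution.
#'
#' @inheritParams simulate_neural
#' @param constants haemodynamic constants.
#' @return list with `bold` (regions x time), `neural`, `dt`, `time`.
#' @export
simulate_bold <- function(net, duration, dt = 0.1, burn_in = 60,
                          seed = NULL, constants = hemo_constants()) {
  sim <- simulate_neural(net, duration, dt, burn_in, seed)
  bold <- hemodynamic_response(sim$states, dt, net$hemo_scale, constants)
  list(bold = bold, neural = sim$states, time = sim$time, dt = dt)
}

#' Sample runs from a continuous BOLD series
#'
#' Decimates to the TR grid, adds observation noise with spectrum
#' `noise_amp * f^(-noise_exp)`, splits into runs, and injects random
#' per-run intensity offsets so that run-concatenation correction is
#' exercised downstream.
#'
#' @param bold list from [simulate_bold()] (or any list with `bold`, `dt`).
#' @param net the generating [ground_truth_network()] (for noise spectra
#'   and labels).
#' @param acq an [acquisition_spec()].
#' @return list of [run_timeseries()] objects, one per run, with the
#'   acquisition echoed in an attribute.
#' @export
sample_runs <- function(bold, net, acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  step <- acq$tr_seconds / bold$dt
  if (abs(step - round(step)) > 1e-8)
    stopf("tr_seconds must be an integer multiple of the simulation step")
  step <- round(step)
  n_vol <- acq$n_runs * acq$volumes_per_run
  need <- n_vol * step
  if (ncol(bold$bold) < need)
    stopf("BOLD series too short: need %d samples (%.0f s), have %d",
          need, need * bold$dt, ncol(bold$bold))
  idx <- seq(1L, by = step, length.out = n_vol)
  y <- bold$bold[, idx, drop = FALSE]
  n <- nrow(y)
  runs <- with_seed(derive_seed(acq$seed, "sample_runs"), {
    for (r in seq_len(n))
      y[r, ] <- y[r, ] + powerlaw_series(n_vol, acq$tr_seconds,
                                         net$noise_amp[r], net$noise_exp[r])
    lapply(seq_len(acq$n_runs), function(k) {
      cols <- (k - 1L) * acq$volumes_per_run + seq_len(acq$volumes_per_run)
      vals <- y[, cols, drop = FALSE] +
        stats::rnorm(n, 0, acq$run_offset_sd)   # per-region, per-run offset
      run_timeseries(vals, tr_seconds = acq$tr_seconds,
                     run_id = paste0("run-", k), labels = net$labels)
    })
  })
  attr(runs, "acquisition") <- acq
  runs
}

#' End-to-end synthetic dataset
#'
#' Simulates one continuous recording long enough for the requested
#' acquisition and samples it into runs.
#'
#' @inheritParams sample_runs
#' @param dt,burn_in,constants forwarded to [simulate_bold()].
#' @return list with `runs`, `bold`, and the generating `net` and `acq`.
#' @export
simulate_dataset <- function(net = soz_network(), acq = acquisition_spec(),
                             dt = 0.1, burn_in = 60,
                             constants = hemo_constants()) {
  duration <- acq$n_runs * acq$volumes_per_run * acq$tr_seconds
  bold <- simulate_bold(net, duration, dt, burn_in,
                        seed = derive_seed(acq$seed, "simulate_bold"),
                        constants = constants)
  runs <- sample_runs(bold, net, acq)
  list(runs = runs, bold = bold, net = net, acq = acq)
}

#' Spread a region series over noisy voxels
#'
#' Builds a voxel x time matrix in which every voxel is a weighted copy of
#' the input series plus independent Gaussian noise; a fixture generator
#' for eigenvariate extraction.
#'
#' @param series numeric vector (one region's time course).
#' @param n_voxels number of voxels (>= 1).
#' @param weights per-voxel weights, recycled to `n_voxels`.
#' @param noise_sd standard deviation of the added noise.
#' @param seed RNG seed; `NULL` uses the current state.
#' @return matrix (voxels x time).
#' @export
make_roi_voxels <- function(series, n_voxels, weights = 1, noise_sd = 0,
                            seed = NULL) {
  stopifnot(n_voxels >= 1, all(is.finite(weights)), noise_sd >= 0)
  weights <- rep_len(weights, n_voxels)
  with_seed(seed, {
    m <- outer(weights, as.numeric(series))
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
    m
  })
}
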