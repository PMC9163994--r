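## ---- run time series, concatenation, eigenvariates, MAR cross-spectra ----

#' Run time series
#'
#' Container for one run of sampled BOLD values: a series x volumes matrix
#' with repetition time, run identity and series labels.
#'
#' @param values numeric matrix (series x volumes) or vector.
#' @param tr_seconds repetition time (s).
#' @param run_id run identifier.
#' @param labels one label per series.
#' @export
run_timeseries <- function(values, tr_seconds, run_id = "run-1",
                           labels = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stopf("run '%s' contains non-finite values", run_id)
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stopf("need one label per series (%d labels, %d series)",
          length(labels), nrow(values))
  rownames(values) <- labels
  structure(list(values = values, tr_seconds = tr_seconds,
                 run_id = run_id, labels = labels),
            class = "run_timeseries")
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf("<run_timeseries> %s: %d series x %d volumes, TR %g s\n",
              x$run_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Concatenate runs with intensity correction
#'
#' Removes the per-run mean (and, optionally, a per-run linear drift) from
#' every series and joins the runs in order, retaining the boundary indices
#' so later stages know where sessions meet.  This corrects for intensity
#' differences between scanning sessions.
#'
#' @param runs list of [run_timeseries()] sharing TR and labels.
#' @param remove_drift also remove a per-run linear trend.
#' @return a [run_timeseries()] with attribute `boundaries`: the first
#'   volume index of each run in the concatenated series.
#' @export
concatenate_runs <- function(runs, remove_drift = FALSE) {
  stopifnot(length(runs) >= 1)
  trs <- vapply(runs, function(r) r$tr_seconds, numeric(1))
  if (length(unique(trs)) != 1L) stopf("runs have mismatched TR: %s",
                                       paste(unique(trs), collapse = ", "))
  labs <- lapply(runs, function(r) r$labels)
  if (!all(vapply(labs, identical, logical(1), labs[[1L]])))
    stopf("runs have mismatched series labels")
  centred <- lapply(runs, function(r) {
    v <- r$values
    n <- ncol(v)
    if (remove_drift && n > 2) {
      tt <- seq_len(n)
      v <- t(apply(v, 1L, function(y) stats::residuals(stats::lm.fit(
        cbind(1, tt), y))))
    } else {
      v <- v - rowMeans(v)
    }
    v
  })
  lens <- vapply(centred, ncol, integer(1))
  out <- run_timeseries(do.call(cbind, centred), tr_seconds = trs[1L],
                        run_id = "concatenated", labels = labs[[1L]])
  attr(out, "boundaries") <- cumsum(c(1L, lens[-length(lens)]))
  attr(out, "run_lengths") <- lens
  out
}

#' First eigenvariate of an ROI
#'
#' Summarizes a voxel x time matrix as its first singular time course,
#' after a permissive voxel-wise F-test against the effects-of-interest
#' design (run-boundary regressors, i.e. a per-run intercept).  Voxels with
#' `p < p_threshold` are retained; if none survive, a first-class
#' "no extractable signal" outcome is returned (the post-operative
#' obliterated-SOZ pathway), not an error.
#'
#' @param voxels numeric matrix (voxels x time).
#' @param p_threshold F-test retention threshold, default 0.5.
#' @param run_lengths volumes per run, defining the effects-of-interest
#'   design; default a single run.
#' @return list of class `eigenvariate` with `status` ("ok" or
#'   "no-signal"), `series` (unit-scaled first singular time course),
#'   `weights` (unit-norm, mean weight >= 0), `retained` (voxel indices),
#'   `p_values`.
#' @export
extract_eigenvariate <- function(voxels, p_threshold = 0.5,
                                 run_lengths = NULL) {
  voxels <- as.matrix(voxels)
  if (length(voxels) == 0L || ncol(voxels) < 2L)
    stopf("empty or degenerate voxel matrix")
  if (p_threshold <= 0 || p_threshold > 1)
    stopf("p_threshold must be in (0, 1]")
  nt <- ncol(voxels)
  if (is.null(run_lengths)) run_lengths <- nt
  if (sum(run_lengths) != nt) stopf("run_lengths must sum to %d", nt)
  ## effects of interest: one intercept regressor per run
  X <- matrix(0, nt, length(run_lengths))
  pos <- cumsum(c(0L, run_lengths))
  for (k in seq_along(run_lengths))
    X[(pos[k] + 1L):pos[k + 1L], k] <- 1
  p <- ncol(X); df2 <- nt - p
  XtXi <- solve(crossprod(X))
  B <- voxels %*% X %*% XtXi                 # voxel-wise effect estimates
  fit <- B %*% t(X)
  rss <- rowSums((voxels - fit)^2)
  ess <- rowSums(fit^2)
  fstat <- (ess / p) / pmax(rss / df2, .Machine$double.eps)
  pval <- stats::pf(fstat, p, df2, lower.tail = FALSE)
  keep <- which(pval < p_threshold)
  if (length(keep) == 0L)
    return(structure(list(status = "no-signal", series = NULL,
                          weights = NULL, retained = integer(0),
                          p_values = pval),
                     class = "eigenvariate"))
  Y <- voxels[keep, , drop = FALSE]
  Y <- Y - rowMeans(Y)                       # centre before SVD
  sv <- svd(Y, nu = 1L, nv = 1L)
  w <- sv$u[, 1L]
  if (mean(w) < 0) w <- -w                   # sign convention
  series <- as.vector(crossprod(w, Y))
  structure(list(status = "ok", series = series, weights = w,
                 retained = keep, p_values = pval,
                 singular_values = sv$d),
            class = "eigenvariate")
}

#' Default frequency grid
#'
#' 32 linear bins spanning 1/128 Hz to the Nyquist frequency of the given
#' repetition time.
#'
#' @param tr_seconds repetition time (s).
#' @param n_bins number of bins.
#' @export
default_freq_grid <- function(tr_seconds, n_bins = 32L) {
  seq(1 / 128, 1 / (2 * tr_seconds), length.out = n_bins)
}

#' Cross-spectral density container
#'
#' Hermitian complex spectral matrices on a frequency grid; the data
#' feature consumed by the spectral DCM.
#'
#' @param freq_hz strictly increasing grid in (0, Nyquist].
#' @param matrices complex array (n x n x n_freq).
#' @param mar_order autoregression order used (0 if analytic).
#' @param n_samples_used number of time samples behind the estimate.
#' @param labels region labels.
#' @param scales per-region standardization scales applied upstream.
#' @export
cross_spectral_density <- function(freq_hz, matrices, mar_order = 0L,
                                   n_samples_used = 0L, labels = NULL,
                                   scales = NULL) {
  stopifnot(all(diff(freq_hz) > 0), all(freq_hz > 0))
  d <- dim(matrices)
  stopifnot(length(d) == 3L, d[1] == d[2], d[3] == length(freq_hz))
  asym <- max(vapply(seq_len(d[3]), function(k)
    max(Mod(matrices[, , k] - Conj(t(matrices[, , k])))), numeric(1)))
  if (asym > 1e-10) stopf("CSD not Hermitian (max asymmetry %.3g)", asym)
  if (is.null(labels)) labels <- paste0("R", seq_len(d[1]))
  structure(list(freq_hz = freq_hz, matrices = matrices,
                 mar_order = as.integer(mar_order),
                 n_samples_used = as.integer(n_samples_used),
                 labels = labels, scales = scales),
            class = "cross_spectral_density")
}

#' @export
print.cross_spectral_density <- function(x, ...) {
  cat(sprintf(
    "<cross_spectral_density> %d regions, %d frequencies [%.4g, %.4g] Hz (MAR order %d)\n",
    dim(x$matrices)[1], length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
    x$mar_order))
  invisible(x)
}

#' MAR-based cross-spectral density estimate
#'
#' Fits a multivariate autoregression of the stated order by
#' ridge-regularized least squares (series standardized internally to unit
#' variance; scales recorded) and evaluates the parametric spectral matrix
#' `S(f) = A(f)^-1 Sigma A(f)^-H` with
#' `A(f) = I - sum_k A_k exp(-2 pi i f k TR)` on the requested grid, in
#' two-sided power-spectral-density units ((signal units)^2 s).
#'
#' @param series a [run_timeseries()] (typically the concatenated run).
#' @param order MAR order; the series must be longer than `4 * order`.
#' @param freq_hz frequency grid; default [default_freq_grid()].
#' @param ridge ridge penalty on the MAR coefficients.
#' @return a [cross_spectral_density()].
#' @export
estimate_csd_mar <- function(series, order = 8L,
                             freq_hz = default_freq_grid(series$tr_seconds),
                             ridge = 1e-6) {
  stopifnot(inherits(series, "run_timeseries"))
  Y <- series$values
  n <- nrow(Y); nt <- ncol(Y)
  if (nt <= 4L * order)
    stopf("series length %d too short for MAR order %d (need > %d)",
          nt, order, 4L * order)
  sc <- apply(Y, 1L, stats::sd)
  if (any(sc == 0)) stopf("constant series cannot be standardized")
  Y <- (Y - rowMeans(Y)) / sc
  ## design: lagged predictors, response the current sample
  resp <- t(Y[, (order + 1L):nt, drop = FALSE])
  X <- do.call(cbind, lapply(seq_len(order), function(k)
    t(Y[, (order + 1L - k):(nt - k), drop = FALSE])))
  XtX <- crossprod(X) + diag(ridge, ncol(X))
  coef <- tryCatch(solve(XtX, crossprod(X, resp)),
                   error = function(e)
                     stopf("singular MAR regression; try a lower order"))
  E <- resp - X %*% coef
  sigma <- crossprod(E) / nrow(E)
  tr <- series$tr_seconds
  A_k <- lapply(seq_len(order), function(k)
    t(coef[(k - 1L) * n + seq_len(n), , drop = FALSE]))
  S <- array(complex(real = 0), dim = c(n, n, length(freq_hz)))
  for (j in seq_along(freq_hz)) {
    Af <- diag(1 + 0i, n)
    for (k in seq_len(order))
      Af <- Af - A_k[[k]] * exp(-2i * pi * freq_hz[j] * k * tr)
    Ai <- solve(Af)
    Sj <- Ai %*% (sigma * tr) %*% Conj(t(Ai))
    S[, , j] <- (Sj + Conj(t(Sj))) / 2       # Hermitian-symmetrize
  }
  cross_spectral_density(freq_hz, S, mar_order = order,
                         n_samples_used = nt, labels = series$labels,
                         scales = sc)
}
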