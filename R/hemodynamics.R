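#' Canonical haemodynamic constants
#'
#' Balloon-model constants used throughout the package: vasodilatory signal
#' decay `kappa` (1/s), flow autoregulation `gamma` (1/s), mean transit time
#' `tau` (s), vessel stiffness exponent `alpha` (dimensionless) and resting
#' oxygen extraction fraction `e0`.  Only a per-region log-gain on the
#' response is estimated during model inversion; the shape constants stay
#' fixed because two-node spectra cannot constrain a full haemodynamic
#' parameterization.
#'
#' @param kappa,gamma,tau,alpha,e0,v0 balloon-model constants; `v0` is the
#'   resting venous volume fraction entering the BOLD observation equation.
#' @return a named list of class `hemo_constants`.
#' @export
hemo_constants <- function(kappa = 0.64, gamma = 0.32, tau = 2,
                           alpha = 0.32, e0 = 0.4, v0 = 0.04) {
  stopifnot(kappa > 0, gamma > 0, tau > 0, alpha > 0, alpha < 1,
            e0 > 0, e0 < 1, v0 > 0)
  structure(list(kappa = kappa, gamma = gamma, tau = tau,
                 alpha = alpha, e0 = e0, v0 = v0),
            class = "hemo_constants")
}

#' Haemodynamic response to a neural time series
#'
#' Integrates the balloon model per region, driven by the neural state, and
#' returns the BOLD signal-change series.  A fourth-order Runge-Kutta
#' scheme is used with the neural drive linearly interpolated at half
#' steps; the same routine driven by a unit impulse supplies the frequency
#' response used by the spectral generative model, so simulation and model
#' prediction are self-consistent by construction.
#'
#' @param neural matrix (regions x time) of neural states, or a vector for
#'   one region.
#' @param dt time step of `neural` in seconds.
#' @param hemo_scale per-region dimensionless gain applied to the output.
#' @param constants a [hemo_constants()] object.
#' @return matrix (regions x time) of BOLD signal change.
#' @export
hemodynamic_response <- function(neural, dt, hemo_scale = 1,
                                 constants = hemo_constants()) {
  if (is.vector(neural)) neural <- matrix(neural, nrow = 1L)
  n <- nrow(neural); nt <- ncol(neural)
  hemo_scale <- rep_len(hemo_scale, n)
  hc <- constants
  k1c <- 7 * hc$e0; k2c <- 2; k3c <- 2 * hc$e0 - 0.2
  ia <- 1 / hc$alpha; ie <- 1 / hc$e0; it <- 1 / hc$tau
  ## state vectors: s (vasodilatory signal), f (inflow), v (volume),
  ## q (deoxyhaemoglobin); derivatives inlined for speed
  s <- numeric(n); f <- v <- q <- rep(1, n)
  y <- matrix(0, n, nt)
  kap <- hc$kappa; gam <- hc$gamma; oe <- 1 - hc$e0
  deriv <- function(s, f, v, q, x) {
    fv <- v^ia
    list(x - kap * s - gam * (f - 1),
         s,
         (f - fv) * it,
         (f * (1 - oe^(1 / f)) * ie - fv * q / v) * it)
  }
  for (t in seq_len(nt - 1L)) {
    x0 <- neural[, t]; x1 <- neural[, t + 1L]; xm <- (x0 + x1) / 2
    k1 <- deriv(s, f, v, q, x0)
    k2 <- deriv(s + dt / 2 * k1[[1]], f + dt / 2 * k1[[2]],
                v + dt / 2 * k1[[3]], q + dt / 2 * k1[[4]], xm)
    k3 <- deriv(s + dt / 2 * k2[[1]], f + dt / 2 * k2[[2]],
                v + dt / 2 * k2[[3]], q + dt / 2 * k2[[4]], xm)
    k4 <- deriv(s + dt * k3[[1]], f + dt * k3[[2]],
                v + dt * k3[[3]], q + dt * k3[[4]], x1)
    s <- s + dt / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]])
    f <- f + dt / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]])
    v <- v + dt / 6 * (k1[[3]] + 2 * k2[[3]] + 2 * k3[[3]] + k4[[3]])
    q <- q + dt / 6 * (k1[[4]] + 2 * k2[[4]] + 2 * k3[[4]] + k4[[4]])
    if (any(!is.finite(q)) || any(!is.finite(v)))
      stopf("haemodynamic integration diverged in region %d at t = %.1f s",
            which(!is.finite(q + v))[1L], t * dt)
    y[, t + 1L] <- k1c * (1 - q) + k2c * (1 - q / v) + k3c * (1 - v)
  }
  y * (hc$v0 * hemo_scale)
}

#' Haemodynamic impulse response
#'
#' BOLD response to a small neural impulse at time zero, normalized to
#' unit impulse area.  The default area (0.01) keeps the balloon model in
#' its linear regime, so the normalized response is the small-signal
#' linearization used, after a Fourier transform, as the haemodynamic
#' frequency response of the generative model.  A unit-area impulse
#' (area 1) drives the model well into its nonlinear range and is only
#' meaningful for qualitative shape checks.
#'
#' @param dt integration step (s).
#' @param duration length of the returned response (s).
#' @param area impulse area (integral of the neural drive).
#' @inheritParams hemodynamic_response
#' @return list with `time` and `response` vectors (response scaled to
#'   unit area).
#' @export
hemodynamic_impulse <- function(dt = 0.1, duration = 64, area = 0.01,
                                constants = hemo_constants()) {
  nt <- ceiling(duration / dt)
  x <- matrix(0, 1L, nt)
  ## short rectangular pulse of fixed physical duration (0.4 s), so the
  ## response is step-size independent; the integrator interpolates the
  ## drive linearly between samples, hence a K-sample rectangle starting
  ## at the first sample has effective area (K - 1/2) * a * dt
  K <- max(2L, round(0.4 / dt))
  x[1L, seq_len(K)] <- area / ((K - 0.5) * dt)
  y <- hemodynamic_response(x, dt, constants = constants)
  list(time = (seq_len(nt) - 1L) * dt, response = drop(y) / area)
}

## cache of haemodynamic transfer functions keyed by constants/grid
.hemo_cache <- new.env(parent = emptyenv())

#' Haemodynamic frequency response
#'
#' Discrete-time Fourier transform of the impulse response, evaluated on an
#' arbitrary frequency grid (Hz).  Cached, since the constants are fixed
#' during inversion.
#'
#' @param freq_hz frequency grid in Hz.
#' @inheritParams hemodynamic_impulse
#' @return complex vector `h(f)` of the same length as `freq_hz`.
#' @export
hemodynamic_transfer <- function(freq_hz, dt = 0.1, duration = 64,
                                 constants = hemo_constants()) {
  key <- paste(c(unlist(constants), dt, duration, signif(freq_hz, 12)),
               collapse = ",")
  hit <- .hemo_cache[[key]]
  if (!is.null(hit)) return(hit)
  imp <- hemodynamic_impulse(dt = dt, duration = duration, constants = constants)
  ph <- exp(outer(freq_hz, imp$time, function(f, t) -2i * pi * f * t))
  h <- as.vector(ph %*% imp$response) * dt
  .hemo_cache[[key]] <- h
  h
}
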