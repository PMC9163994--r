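#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Integer rounding in which ties at .5 move away from zero (137.5 -> 138,
#' -37.5 -> -38), the convention used for all reported integer percentages.
#' Base [round()] rounds half to even and would report 87.5% as 88 only by
#' accident of floating point.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## log-determinant of a symmetric positive-definite matrix via Cholesky;
## falls back to eigenvalues (clamped) when the Cholesky fails marginally.
logdet <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) {
    2 * sum(log(diag(ch)))
  } else {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    sum(log(pmax(ev, .Machine$double.eps)))
  }
}

## symmetrize and invert an SPD matrix, with a tiny jitter ladder
inv_spd <- function(M, jitter = 0) {
  M <- (M + t(M)) / 2
  for (j in c(jitter, 1e-12, 1e-10, 1e-8)) {
    Mi <- tryCatch(chol2inv(chol(M + diag(j, nrow(M)))), error = function(e) NULL)
    if (!is.null(Mi)) return((Mi + t(Mi)) / 2)
  }
  Mi <- solve(M + diag(1e-6, nrow(M)))
  (Mi + t(Mi)) / 2
}

## derive a child RNG seed from a master seed and a stream label;
## deterministic, documented scheme: sum of utf8 codes of the label mixed
## with the master seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## all eigenvalue real parts strictly negative?
is_stable <- function(A, margin = 0) {
  all(Re(eigen(A, only.values = TRUE)$values) < -margin)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stopf("`%s` must be a single probability in (0, 1), got %s", name, format(x))
  invisible(x)
}
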