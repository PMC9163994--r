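## ---- diagnostic-accuracy evaluation of directionality calls ----

#' Contingency counts
#'
#' Aggregated connection-unit counts for diagnostic evaluation.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @export
contingency_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    stopf("counts must be non-negative integers")
  structure(as.list(v), class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("<contingency_counts> TP %d  FP %d  FN %d  TN %d (total %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Aggregate directionality outcomes into contingency counts
#'
#' Pre-operatively each of the two connections counts as one unit:
#' significant expected polarity is a true positive, significant reversed
#' polarity a false positive, and a non-significant connection a false
#' negative (default) or false positive according to `ns_policy`.
#' Post-operatively each subject contributes a single marker weighted by
#' two (covering both connections): BNI above the threshold, or an
#' obliterated SOZ with no signal, counts two true negatives; BNI at or
#' below the threshold counts two false positives.
#'
#' @param pre_calls list of `directionality_call` objects (pre-operative).
#' @param post_records list of [recovery_record()] objects
#'   (post-operative), each with a BNI or the obliterated flag.
#' @param ns_policy where non-significant pre-operative connections go:
#'   `"fn"` (default), `"fp"`, or a logical vector/list keyed by call
#'   index routing individual connections to FP.
#' @param bni_threshold percent, default 70.
#' @return a [contingency_counts()].
#' @export
aggregate_contingency <- function(pre_calls, post_records,
                                  ns_policy = "fn", bni_threshold = 70) {
  tp <- fp <- fn <- tn <- 0L
  for (k in seq_along(pre_calls)) {
    call <- pre_calls[[k]]
    pol <- call$polarity
    for (j in seq_len(nrow(pol))) {
      ## expected polarity: positive out of the presumed SOZ (row 1),
      ## negative back toward it (row 2)
      expected_sign <- if (j == 1L) 1 else -1
      if (pol$significant[j]) {
        if (sign(pol$value[j]) == expected_sign) tp <- tp + 1L
        else fp <- fp + 1L
      } else {
        to_fp <- if (identical(ns_policy, "fp")) TRUE
        else if (identical(ns_policy, "fn")) FALSE
        else isTRUE(ns_policy[[k]][j])
        if (to_fp) fp <- fp + 1L else fn <- fn + 1L
      }
    }
  }
  for (rec in post_records) {
    if (isTRUE(rec$obliterated)) { tn <- tn + 2L; next }
    bni <- compute_bni(rec, bni_threshold)
    if (is.na(bni$bni))
      stopf("post-operative record for subject %s has neither a BNI nor the obliterated flag",
            rec$subject %||% "?")
    if (bni$bni > bni_threshold) tn <- tn + 2L else fp <- fp + 2L
  }
  contingency_counts(tp, fp, fn, tn)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(lower, upper)` (proportions).
#' @export
binomial_exact_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stopf("need integers 0 <= k <= n with n >= 1")
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and negative
#' predictive value `TN/(TN+FN)`, each reported as an integer percent
#' (half away from zero) with a 95% exact binomial confidence interval.
#' Metrics with a zero denominator are reported as `NA` (undefined), not
#' zero.
#'
#' @param counts a [contingency_counts()].
#' @param level confidence level for the intervals.
#' @return data frame with metric, numerator, denominator, percent
#'   (integer), ci_lower, ci_upper (percent, unrounded).
#' @export
diagnostic_metrics <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "contingency_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) stopf("empty contingency table")
  defs <- list(
    accuracy = c(tp + tn, total),
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn))
  rows <- lapply(names(defs), function(m) {
    k <- defs[[m]][1L]; n <- defs[[m]][2L]
    if (n == 0)
      return(data.frame(metric = m, numerator = k, denominator = n,
                        percent = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_))
    ci <- binomial_exact_ci(k, n, level)
    data.frame(metric = m, numerator = k, denominator = n,
               percent = round_half_up(100 * k / n),
               ci_lower = 100 * ci[["lower"]],
               ci_upper = 100 * ci[["upper"]])
  })
  do.call(rbind, rows)
}

#' Prevalence-adjusted bias-adjusted kappa
#'
#' `PABAK = 2 Po - 1` with observed agreement `Po = (TP + TN) / total`.
#'
#' @param counts a [contingency_counts()].
#' @return kappa value in `[-1, 1]`.
#' @export
pabak <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0) stopf("empty contingency table")
  2 * (counts$tp + counts$tn) / total - 1
}
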