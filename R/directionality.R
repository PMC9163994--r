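## ---- seizure-network directionality, recovery indices, BNI ----

#' Connection estimate
#'
#' A single directed coupling with its posterior probability.
#'
#' @param source,target region labels.
#' @param value coupling in Hz.
#' @param pp posterior probability in `[0, 1]`.
#' @param phase `"pre"` or `"post"`.
#' @export
connection_estimate <- function(source, target, value, pp,
                                phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (pp < 0 || pp > 1) stopf("pp must be in [0, 1]")
  structure(list(source = source, target = target, value = value,
                 pp = pp, phase = phase), class = "connection_estimate")
}

#' Classify seizure-onset versus propagation zone from polarity
#'
#' Applies the directionality rule: the seizure-onset zone (SOZ) emits
#' excitatory (positive) coupling toward the propagation zone (pZ) and
#' receives inhibitory (negative) coupling back.  Each significant
#' connection (posterior probability above the threshold) votes for a
#' candidate SOZ: a positive coupling nominates its source, a negative
#' coupling its target.  Consistent votes yield a call; the status is
#' `"expected"` when the called SOZ is the first (clinically presumed)
#' node and `"reversed"` when it is the second.  No significant
#' connection, or conflicting votes, yields `"indeterminate"` with no
#' call.
#'
#' @param forward [connection_estimate()] from the presumed SOZ to the
#'   presumed pZ.
#' @param backward [connection_estimate()] in the return direction.
#' @param pp_threshold significance threshold, default 0.9.
#' @return list of class `directionality_call`: `soz`, `pz` (labels or
#'   `NA`), `status`, `polarity` (per-connection record).
#' @export
classify_direction <- function(forward, backward, pp_threshold = 0.9) {
  assert_prob(pp_threshold, "pp_threshold")
  for (cn in list(forward, backward))
    if (identical(cn$source, cn$target))
      stopf("self-connection (%s) passed to classify_direction", cn$source)
  if (!identical(forward$source, backward$target) ||
      !identical(forward$target, backward$source))
    stopf("the two estimates must connect the same pair of nodes")
  presumed <- forward$source
  other <- forward$target
  polarity <- data.frame(
    source = c(forward$source, backward$source),
    target = c(forward$target, backward$target),
    value = c(forward$value, backward$value),
    pp = c(forward$pp, backward$pp),
    significant = c(forward$pp, backward$pp) > pp_threshold)
  ## each significant connection nominates an SOZ candidate
  votes <- character(0)
  if (polarity$significant[1L])
    votes <- c(votes, if (forward$value > 0) forward$source else
      forward$target)
  if (polarity$significant[2L])
    votes <- c(votes, if (backward$value > 0) backward$source else
      backward$target)
  if (length(votes) == 0L || length(unique(votes)) > 1L) {
    status <- "indeterminate"
    soz <- pz <- NA_character_
  } else {
    soz <- votes[1L]
    pz <- if (identical(soz, presumed)) other else presumed
    status <- if (identical(soz, presumed)) "expected" else "reversed"
  }
  structure(list(soz = soz, pz = pz, status = status, polarity = polarity,
                 pp_threshold = pp_threshold),
            class = "directionality_call")
}

#' Recovery index
#'
#' Proportional pre-to-post reduction of a coupling,
#' `100 * (pre - post) / pre` (percent).  The same formula serves both
#' directions: a negative pre-operative inhibition that weakens
#' post-operatively yields a positive index.  Rounding to integers
#' (half away from zero) is applied only at reporting, via
#' [round_half_up()].
#'
#' @param pre,post coupling values in Hz; `pre` must be nonzero
#'   (|pre| > 1e-6).
#' @return unrounded percent.
#' @export
recovery_index <- function(pre, post) {
  if (any(abs(pre) < 1e-6))
    stopf("recovery index undefined for zero pre-operative coupling")
  100 * (pre - post) / pre
}

#' Pre/post recovery record for one subject
#'
#' Collects pre- and post-operative SOZ->pZ excitation and pZ->SOZ
#' inhibition, derives the qualitative change flags, both recovery
#' indices (reported as integers, half away from zero) and the
#' Boerwinkle Neuroplasticity Index (BNI), the sum of the two reported
#' indices.  An obliterated record (no extractable post-operative SOZ
#' signal) carries no indices and an undefined BNI.
#'
#' @param subject subject identifier.
#' @param pre_excitation,post_excitation SOZ->pZ coupling (Hz).
#' @param pre_inhibition,post_inhibition pZ->SOZ coupling (Hz).
#' @param obliterated no extractable post-operative SOZ signal.
#' @return list of class `recovery_record`.
#' @export
recovery_record <- function(subject, pre_excitation = NA,
                            post_excitation = NA, pre_inhibition = NA,
                            post_inhibition = NA, obliterated = FALSE) {
  if (obliterated) {
    return(structure(list(subject = subject, obliterated = TRUE,
                          pre_excitation = pre_excitation,
                          pre_inhibition = pre_inhibition,
                          post_excitation = NA_real_,
                          post_inhibition = NA_real_,
                          reduced_excitation = NA, became_inhibitory = NA,
                          reduced_inhibition = NA, became_excitatory = NA,
                          soz_recovery_index = NA_real_,
                          pz_recovery_index = NA_real_, bni = NA_real_),
                     class = "recovery_record"))
  }
  vals <- c(pre_excitation, post_excitation, pre_inhibition,
            post_inhibition)
  if (any(is.na(vals)))
    stopf("subject %s: all four couplings are required unless obliterated",
          subject)
  soz_ri <- round_half_up(recovery_index(pre_excitation, post_excitation))
  pz_ri <- round_half_up(recovery_index(pre_inhibition, post_inhibition))
  structure(list(
    subject = subject, obliterated = FALSE,
    pre_excitation = pre_excitation, post_excitation = post_excitation,
    pre_inhibition = pre_inhibition, post_inhibition = post_inhibition,
    reduced_excitation = post_excitation < pre_excitation,
    became_inhibitory = post_excitation < 0,
    reduced_inhibition = post_inhibition > pre_inhibition,
    became_excitatory = post_inhibition > 0,
    soz_recovery_index = soz_ri, pz_recovery_index = pz_ri,
    bni = round_half_up(soz_ri + pz_ri)), class = "recovery_record")
}

#' Boerwinkle Neuroplasticity Index and outcome prediction
#'
#' The BNI is the sum of the SOZ and pZ recovery indices; residual
#' activity is predicted to be below the seizure threshold when BNI
#' exceeds 70% or the SOZ was obliterated (no signal at all).
#'
#' @param record a [recovery_record()], or a list with
#'   `soz_recovery_index`, `pz_recovery_index` and optionally
#'   `obliterated`.
#' @param threshold percent threshold, default 70.
#' @return list with `bni` (percent, `NA` if obliterated) and
#'   `sub_seizure_threshold` (logical prediction).
#' @export
compute_bni <- function(record, threshold = 70) {
  obl <- isTRUE(record$obliterated)
  if (obl)
    return(list(bni = NA_real_, sub_seizure_threshold = TRUE,
                obliterated = TRUE))
  si <- record$soz_recovery_index; pi_ <- record$pz_recovery_index
  if (is.null(si) || is.null(pi_) || is.na(si) || is.na(pi_))
    stopf("recovery indices missing and record not flagged obliterated")
  bni <- round_half_up(si + pi_)
  list(bni = bni, sub_seizure_threshold = bni > threshold,
       obliterated = FALSE)
}

#' Summarize recovery records across subjects
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' each quantitative measure, rounded to integers (half away from zero)
#' as reported.
#'
#' @param records list of [recovery_record()] objects.
#' @param measures measures to summarize.
#' @return data frame with measure, n, mean, sd.
#' @export
summarize_records <- function(records,
                              measures = c("soz_recovery_index",
                                           "pz_recovery_index", "bni")) {
  vals <- lapply(measures, function(m)
    stats::na.omit(vapply(records, function(r)
      as.numeric(r[[m]] %||% NA_real_), numeric(1))))
  ns <- vapply(vals, length, integer(1))
  if (any(ns < 2L))
    stopf("need at least 2 values per measure to compute an SD")
  data.frame(measure = measures, n = ns,
             mean = round_half_up(vapply(vals, mean, numeric(1))),
             sd = round_half_up(vapply(vals, stats::sd, numeric(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference cohort: pre/post-operative couplings
#'
#' The bundled reference cohort of nine operated hypothalamic-hamartoma
#' patients with pre- and post-operative two-node coupling estimates
#' (SOZ->pZ excitation and pZ->SOZ inhibition, Hz, two-decimal
#' precision), as published for this patient group, plus the four
#' subjects whose SOZ was obliterated.  Used by the worked examples and
#' the reproduction checks.
#'
#' @param include_obliterated append the obliterated subjects (couplings
#'   `NA`).
#' @return data frame with subject, volumes, pre/post couplings,
#'   obliterated flag.
#' @export
hh_cohort_prepost <- function(include_obliterated = FALSE) {
  path <- system.file("extdata", "hh_cohort_prepost.csv", package = "rsdcm",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!include_obliterated) d <- d[!d$obliterated, ]
  d
}

#' Recovery records for the reference cohort
#'
#' @inheritParams hh_cohort_prepost
#' @return list of [recovery_record()] objects.
#' @export
hh_cohort_records <- function(include_obliterated = FALSE) {
  d <- hh_cohort_prepost(include_obliterated)
  lapply(seq_len(nrow(d)), function(i)
    if (d$obliterated[i])
      recovery_record(d$subject[i], obliterated = TRUE)
    else
      recovery_record(d$subject[i],
                      pre_excitation = d$pre_excitation[i],
                      post_excitation = d$post_excitation[i],
                      pre_inhibition = d$pre_inhibition[i],
                      post_inhibition = d$post_inhibition[i]))
}
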