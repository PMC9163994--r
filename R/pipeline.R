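## ---- end-to-end pipeline ----

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: acquisition,
#' spectral estimation, posterior-probability thresholds (0.9 for
#' individual connections, 0.95 for group effects, 0.9 for the pre/post
#' hierarchy), the BNI threshold (percent), the non-significant-connection
#' policy, and the master seed from which all stage seeds are derived.
#'
#' @param tr_seconds,volumes_per_run,n_runs acquisition geometry.
#' @param mar_order,n_freq spectral estimation settings.
#' @param pp_individual,pp_group,pp_prepost posterior-probability
#'   thresholds.
#' @param bni_threshold percent BNI threshold.
#' @param ns_policy non-significant pre-operative connections to `"fn"`
#'   or `"fp"`.
#' @param p_threshold eigenvariate voxel retention threshold.
#' @param seed master RNG seed.
#' @param subjects list of subject entries (see [run_pipeline()]).
#' @param simulate optional synthetic-cohort spec
#'   (`list(n_subjects = ..., prepost = ...)`).
#' @param out optional output directory.
#' @export
pipeline_config <- function(tr_seconds = 2, volumes_per_run = 300,
                            n_runs = 2, mar_order = 8, n_freq = 32,
                            pp_individual = 0.9, pp_group = 0.95,
                            pp_prepost = 0.9, bni_threshold = 70,
                            ns_policy = "fn", p_threshold = 0.5,
                            seed = 1, subjects = NULL, simulate = NULL,
                            out = NULL) {
  for (th in c(pp_individual, pp_group, pp_prepost))
    assert_prob(th, "posterior-probability threshold")
  structure(list(tr_seconds = tr_seconds,
                 volumes_per_run = as.integer(volumes_per_run),
                 n_runs = as.integer(n_runs),
                 mar_order = as.integer(mar_order),
                 n_freq = as.integer(n_freq),
                 pp_individual = pp_individual, pp_group = pp_group,
                 pp_prepost = pp_prepost, bni_threshold = bni_threshold,
                 ns_policy = ns_policy, p_threshold = p_threshold,
                 seed = as.integer(seed), subjects = subjects,
                 simulate = simulate, out = out),
            class = "pipeline_config")
}

## stable FNV-1a hash of the serialized configuration, for provenance
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out")], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

## one session: runs (+ optional ROI voxel matrices) -> fit + report
process_session <- function(runs, cfg, rois = NULL, soz_label = NULL) {
  if (!is.null(rois)) {
    lens <- vapply(runs, function(r) ncol(r$values), integer(1))
    series <- list()
    for (lab in names(rois)) {
      ev <- extract_eigenvariate(rois[[lab]], cfg$p_threshold,
                                 run_lengths = lens)
      if (ev$status == "no-signal") {
        if (identical(lab, soz_label))
          return(list(status = "no-signal", region = lab))
        stopf("no extractable signal in non-SOZ region %s", lab)
      }
      series[[lab]] <- ev$series
    }
    total <- do.call(rbind, series)
    pos <- cumsum(c(0L, lens))
    runs <- lapply(seq_along(lens), function(k)
      run_timeseries(total[, (pos[k] + 1L):pos[k + 1L], drop = FALSE],
                     tr_seconds = runs[[k]]$tr_seconds,
                     run_id = runs[[k]]$run_id, labels = names(rois)))
  }
  cc <- concatenate_runs(runs)
  csd <- estimate_csd_mar(cc, order = cfg$mar_order,
                          freq_hz = default_freq_grid(cc$tr_seconds,
                                                      cfg$n_freq))
  fit <- invert_dcm(csd)
  red <- reduce_and_average(fit)
  report <- threshold_connections(red, cfg$pp_individual)
  list(status = "ok", fit = fit, report = report, csd = csd)
}

## directionality call from a thresholded connection report
call_from_report <- function(report, soz_label, pz_label, pp_threshold,
                             phase = "pre") {
  pick <- function(src, tgt) {
    row <- report[!report$self & report$source == src &
                    report$target == tgt, ]
    if (nrow(row) != 1L) stopf("connection %s->%s missing from report",
                               src, tgt)
    connection_estimate(src, tgt, row$value, row$pp, phase)
  }
  classify_direction(pick(soz_label, pz_label), pick(pz_label, soz_label),
                     pp_threshold)
}

#' Run the end-to-end analysis
#'
#' Executes extraction, run concatenation, cross-spectral estimation,
#' model inversion, exhaustive reduction and averaging, directionality
#' classification and, where the inputs allow, the BNI, group PEB (with
#' optional leave-one-out validation), the pre/post hierarchy and the
#' diagnostic evaluation.  Deterministic given the configuration seed.
#'
#' Each subject entry is a list with `id`, optional covariates `engel`
#' and `age`, and per-phase inputs `pre` / `post`, each either
#' `list(tsv = <paths>)` (one region-wise TSV per run) or
#' `list(nifti = <path>, masks = <named paths>)`.  The first region (or
#' mask) is the clinically presumed SOZ.  With `simulate` set in the
#' configuration, a synthetic cohort is generated instead.
#'
#' @param cfg a [pipeline_config()].
#' @return a results bundle (list) with per-subject calls, records, group
#'   and pre/post results, evaluation, and the configuration echo.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  subjects <- cfg$subjects
  if (!is.null(cfg$simulate)) subjects <- simulate_manifest(cfg)
  if (is.null(subjects) || length(subjects) == 0L)
    stopf("no subjects in configuration")

  per_subject <- list()
  for (s in subjects) {
    res <- list(id = s$id)
    for (phase in c("pre", "post")) {
      input <- s[[phase]]
      if (is.null(input)) next
      sess <- tryCatch(
        load_session(input, cfg, s$id, phase),
        error = function(e) stopf("subject %s, %s: %s", s$id, phase,
                                  conditionMessage(e)))
      res[[phase]] <- sess
    }
    if (!is.null(res$pre) && res$pre$status == "ok") {
      labs <- res$pre$fit$labels
      res$call <- call_from_report(res$pre$report, labs[1L], labs[2L],
                                   cfg$pp_individual)
    }
    if (!is.null(res$post)) {
      if (res$post$status == "no-signal") {
        res$record <- recovery_record(s$id, obliterated = TRUE)
      } else if (!is.null(res$pre) && res$pre$status == "ok") {
        pre_c <- coupling_estimates(res$pre$fit)
        post_c <- coupling_estimates(res$post$fit)
        labs <- res$pre$fit$labels
        g <- function(d, src, tgt)
          d$hz[!d$self & d$source == src & d$target == tgt]
        res$record <- recovery_record(
          s$id,
          pre_excitation = g(pre_c, labs[1L], labs[2L]),
          post_excitation = g(post_c, labs[1L], labs[2L]),
          pre_inhibition = g(pre_c, labs[2L], labs[1L]),
          post_inhibition = g(post_c, labs[2L], labs[1L]))
      }
    }
    per_subject[[s$id]] <- res
  }

  bundle <- list(subjects = per_subject)

  ## group PEB when covariates are present
  engel <- vapply(subjects, function(s) s$engel %||% NA_real_, numeric(1))
  age <- vapply(subjects, function(s) s$age %||% NA_real_, numeric(1))
  pre_ok <- vapply(per_subject, function(r)
    !is.null(r$pre) && r$pre$status == "ok", logical(1))
  if (sum(pre_ok) >= 3L && !anyNA(engel[pre_ok])) {
    ids <- names(per_subject)[pre_ok]
    des <- group_design(ids,
                        engel = engel[pre_ok],
                        age = if (anyNA(age[pre_ok])) NULL else age[pre_ok])
    fits <- lapply(per_subject[ids], function(r) r$pre$fit)
    bundle$group <- list(peb = fit_peb(fits, des),
                         report = NULL, loo = NULL)
    bundle$group$report <- group_bmr_bma(bundle$group$peb, cfg$pp_group)
    bundle$group$loo <- loo_crossvalidate(fits, des, "engel")
  }

  ## pre/post hierarchy over subjects with both usable sessions
  both <- vapply(per_subject, function(r)
    !is.null(r$pre) && r$pre$status == "ok" &&
      !is.null(r$post) && r$post$status == "ok", logical(1))
  if (sum(both) >= 2L) {
    ids <- names(per_subject)[both]
    bundle$prepost <- prepost_hierarchy(
      lapply(per_subject[ids], function(r) r$pre$fit),
      lapply(per_subject[ids], function(r) r$post$fit),
      pp_threshold = cfg$pp_prepost)
  }

  ## evaluation whenever any calls or records exist
  calls <- Filter(Negate(is.null), lapply(per_subject, `[[`, "call"))
  records <- Filter(Negate(is.null), lapply(per_subject, `[[`, "record"))
  if (length(calls) || length(records)) {
    counts <- aggregate_contingency(calls, records, cfg$ns_policy,
                                    cfg$bni_threshold)
    bundle$evaluation <- list(counts = counts,
                              metrics = diagnostic_metrics(counts),
                              pabak = pabak(counts))
  }

  bundle$config <- cfg
  bundle$config_hash <- config_hash(cfg)
  if (!is.null(cfg$out)) write_bundle(bundle, cfg$out)
  bundle
}

## load one session's inputs into run time series (+ optional ROIs)
load_session <- function(input, cfg, id, phase) {
  if (!is.null(input$runs)) {            # in-memory (synthetic manifest)
    if (!is.null(input$rois))
      return(process_session(input$runs, cfg, rois = input$rois,
                             soz_label = input$soz_label))
    return(process_session(input$runs, cfg))
  }
  if (!is.null(input$tsv)) {
    runs <- lapply(input$tsv, read_timeseries_tsv,
                   tr_seconds = cfg$tr_seconds)
    return(process_session(runs, cfg))
  }
  if (!is.null(input$nifti)) {
    nd <- read_bold_nifti(input$nifti, input$masks, cfg$tr_seconds)
    nt <- ncol(nd$rois[[1L]])
    lens <- rep(nt %/% cfg$n_runs, cfg$n_runs)
    lens[cfg$n_runs] <- nt - sum(lens[-cfg$n_runs])
    pos <- cumsum(c(0L, lens))
    runs <- lapply(seq_along(lens), function(k)
      run_timeseries(matrix(0, length(nd$rois), lens[k]),
                     tr_seconds = nd$tr_seconds,
                     run_id = paste0("run-", k), labels = names(nd$rois)))
    return(process_session(runs, cfg, rois = nd$rois,
                           soz_label = names(nd$rois)[1L]))
  }
  stopf("session input needs one of: runs, tsv, nifti")
}

## synthetic cohort manifest from cfg$simulate
simulate_manifest <- function(cfg) {
  sim <- cfg$simulate
  n <- sim$n_subjects %||% 2L
  prepost <- isTRUE(sim$prepost)
  lapply(seq_len(n), function(i) {
    id <- sprintf("sim-%02d", i)
    net <- soz_network(a_soz_to_pz = sim$a_soz_to_pz %||% 0.22,
                       a_pz_to_soz = sim$a_pz_to_soz %||% -0.73)
    acq <- acquisition_spec(tr_seconds = cfg$tr_seconds,
                            volumes_per_run = cfg$volumes_per_run,
                            n_runs = cfg$n_runs,
                            seed = derive_seed(cfg$seed, paste0(id, ":pre")))
    entry <- list(id = id, engel = if (i %% 2L) 1 else -1,
                  age = 5 + i,
                  pre = list(runs = simulate_dataset(net, acq)$runs))
    if (prepost) {
      post_net <- soz_network(a_soz_to_pz = sim$post_a_soz_to_pz %||% 1e-3,
                              a_pz_to_soz = sim$post_a_pz_to_soz %||% -0.2)
      acq2 <- acquisition_spec(tr_seconds = cfg$tr_seconds,
                               volumes_per_run = cfg$volumes_per_run,
                               n_runs = cfg$n_runs,
                               seed = derive_seed(cfg$seed,
                                                  paste0(id, ":post")))
      entry$post <- list(runs = simulate_dataset(post_net, acq2)$runs)
    }
    entry
  })
}

## serialize the bundle as JSON/TSV files under `dir`
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, force = TRUE,
    null = "null")
  for (id in names(bundle$subjects)) {
    r <- bundle$subjects[[id]]
    out <- list(id = id, config_hash = bundle$config_hash)
    if (!is.null(r$call))
      out$call <- list(soz = r$call$soz, pz = r$call$pz,
                       status = r$call$status,
                       polarity = r$call$polarity)
    if (!is.null(r$pre) && r$pre$status == "ok")
      out$pre <- list(free_energy = r$pre$fit$free_energy,
                      couplings = coupling_estimates(r$pre$fit),
                      report = r$pre$report)
    if (!is.null(r$post))
      out$post <- if (r$post$status == "ok")
        list(free_energy = r$post$fit$free_energy,
             couplings = coupling_estimates(r$post$fit)) else
        list(status = "no-signal")
    if (!is.null(r$record)) out$record <- unclass(r$record)
    js(out, sprintf("subject-%s.json", id))
  }
  if (!is.null(bundle$evaluation))
    js(list(counts = unclass(bundle$evaluation$counts),
            metrics = bundle$evaluation$metrics,
            pabak = bundle$evaluation$pabak,
            config_hash = bundle$config_hash), "evaluation.json")
  if (!is.null(bundle$group))
    js(list(beta = bundle$group$peb$beta, report = bundle$group$report,
            loo = bundle$group$loo[c("r", "p", "df")],
            config_hash = bundle$config_hash), "group.json")
  if (!is.null(bundle$prepost))
    js(list(report = bundle$prepost$report,
            subjects = bundle$prepost$subjects,
            config_hash = bundle$config_hash), "prepost.json")
  cfg <- bundle$config
  js(c(unclass(cfg)[setdiff(names(cfg), c("subjects", "simulate"))],
       list(hash = bundle$config_hash)), "config.json")
  invisible(dir)
}
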