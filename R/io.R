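## ---- file formats: TSV time series, NIfTI volumes and masks, configs ----

#' Write a run time series as TSV
#'
#' Tab-separated values with a volume-index column and one column per
#' region (header row holds the labels), plus a JSON sidecar carrying the
#' repetition time, run id and any provenance fields supplied.
#'
#' @param run a [run_timeseries()].
#' @param path output TSV path; the sidecar replaces the extension with
#'   `.json`.
#' @param sidecar named list of extra provenance fields (e.g. seed,
#'   ground truth).
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(run, path, sidecar = list()) {
  stopifnot(inherits(run, "run_timeseries"))
  d <- data.frame(volume = seq_len(ncol(run$values)) - 1L,
                  t(run$values), check.names = FALSE)
  colnames(d) <- c("volume", run$labels)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(tr_seconds = run$tr_seconds, run_id = run$run_id,
                 labels = run$labels), sidecar)
  jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run time series from TSV
#'
#' Expects the format of [write_timeseries_tsv()]: header with region
#' labels, first column the volume index.  The repetition time comes from
#' the JSON sidecar or the `tr_seconds` argument; every cell is strictly
#' validated as numeric.
#'
#' @param path TSV path.
#' @param tr_seconds repetition time override (required when no sidecar).
#' @param run_id run identifier override.
#' @return a [run_timeseries()].
#' @export
read_timeseries_tsv <- function(path, tr_seconds = NULL, run_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("%s: no data rows", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  if (ncol < 2L) stopf("%s: need a volume column plus at least one region",
                       path)
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != ncol)
      stopf("%s line %d: %d cells, expected %d", path, i, length(cells),
            ncol)
    v <- suppressWarnings(as.numeric(cells))
    if (any(is.na(v)))
      stopf("%s line %d: non-numeric cell '%s'", path, i,
            cells[which(is.na(v))[1L]])
    v
  })
  m <- do.call(rbind, rows)
  side <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  tr <- tr_seconds %||% meta$tr_seconds
  if (is.null(tr)) stopf("%s: TR unknown (no sidecar and no tr_seconds)",
                         path)
  run_timeseries(t(m[, -1L, drop = FALSE]), tr_seconds = as.numeric(tr),
                 run_id = run_id %||% (meta$run_id %||% basename(path)),
                 labels = header[-1L])
}

#' Write synthetic BOLD as 4D NIfTI with ROI masks
#'
#' Replicates each region's series into a block of voxels and writes a 4D
#' image plus one 3D mask per region, for end-to-end I/O tests.
#'
#' @param runs list of [run_timeseries()] (concatenated along time).
#' @param dir output directory.
#' @param voxels_per_region voxels per region block.
#' @return list with `bold` (image path) and `masks` (named paths).
#' @export
write_bold_nifti <- function(runs, dir, voxels_per_region = 3L) {
  labels <- runs[[1L]]$labels
  n <- length(labels)
  vals <- do.call(cbind, lapply(runs, function(r) r$values))
  nt <- ncol(vals)
  dims <- c(voxels_per_region * n, 1L, 1L)
  arr <- array(0, c(dims, nt))
  for (r in seq_len(n)) {
    rows <- (r - 1L) * voxels_per_region + seq_len(voxels_per_region)
    for (v in rows) arr[v, 1L, 1L, ] <- vals[r, ]
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bold_path <- file.path(dir, "bold.nii")
  img <- RNifti::asNifti(arr)
  img$pixdim[5L] <- runs[[1L]]$tr_seconds
  RNifti::writeNifti(img, bold_path)
  masks <- stats::setNames(vector("list", n), labels)
  for (r in seq_len(n)) {
    m <- array(0, dims)
    m[(r - 1L) * voxels_per_region + seq_len(voxels_per_region), 1L, 1L] <- 1
    mp <- file.path(dir, sprintf("mask-%s.nii", labels[r]))
    RNifti::writeNifti(RNifti::asNifti(m), mp)
    masks[[r]] <- mp
  }
  list(bold = bold_path, masks = unlist(masks))
}

#' Extract ROI voxel matrices from a 4D NIfTI
#'
#' Returns one voxel x time matrix per mask, with deterministic voxel
#' order (ascending linear index).  The repetition time is read from the
#' header and can be overridden.
#'
#' @param path 4D BOLD NIfTI.
#' @param mask_paths named character vector of 3D mask paths.
#' @param tr_seconds optional TR override (s).
#' @return list with `rois` (named list of matrices) and `tr_seconds`.
#' @export
read_bold_nifti <- function(path, mask_paths, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stopf("%s: expected a 4D image, got %dD", path,
                             length(d))
  vox <- prod(d[1:3])
  flat <- matrix(as.vector(img), nrow = vox)   # voxel x time
  tr <- tr_seconds %||% RNifti::pixdim(img)[4L]
  if (is.null(tr) || !is.finite(tr) || tr <= 0)
    stopf("%s: repetition time missing from header; pass tr_seconds", path)
  rois <- lapply(mask_paths, function(mp) {
    m <- RNifti::readNifti(mp)
    dm <- dim(m); dm <- c(dm, rep(1L, max(0L, 3L - length(dm))))[1:3]
    if (!identical(as.integer(dm), as.integer(d[1:3])))
      stopf("mask %s grid %s does not match image grid %s", mp,
            paste(dm, collapse = "x"),
            paste(d[1:3], collapse = "x"))
    if (max(abs(RNifti::xform(m) - RNifti::xform(img))) > 1e-4)
      stopf("mask %s affine does not match the image", mp)
    idx <- which(as.vector(m) != 0)
    if (length(idx) == 0L) stopf("mask %s is empty", mp)
    flat[idx, , drop = FALSE]
  })
  if (is.null(names(rois)))
    names(rois) <- sub("\\.nii(\\.gz)?$", "", basename(mask_paths))
  list(rois = rois, tr_seconds = as.numeric(tr))
}

#' Read a pipeline configuration
#'
#' YAML or JSON, validated minimally; see [pipeline_config()] for the
#' recognized fields.
#'
#' @param path configuration file.
#' @return the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such config: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}
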