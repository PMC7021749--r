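CONTOUR_SCHEMA_VERSION <- "1.0"

#' Write / read contour sets as JSON
#'
#' Schema (versioned): `{version, spacing: [dz, dy, dx], observer_id,
#' slice_count, contours: [{slice, label, hole, vertices: [[x, y], ...]}]}`
#' with vertex coordinates in mm.
#'
#' @param rois an [roi_set()].
#' @param path JSON file path.
#' @return `read_contours()` returns the [roi_set()];
#'   `write_contours()` returns `path` invisibly.
#' @name contour_io
NULL

#' @rdname contour_io
#' @export
write_contours <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  payload <- list(
    version = CONTOUR_SCHEMA_VERSION,
    spacing = rois$spacing,
    observer_id = rois$observer_id,
    slice_count = rois$slice_count,
    contours = lapply(rois$contours, function(c)
      list(slice = c$slice, label = c$label, hole = c$hole,
           vertices = unname(apply(c$vertices, 1L, as.numeric, simplify = FALSE)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname contour_io
#' @export
read_contours <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$version, CONTOUR_SCHEMA_VERSION))
    stopf("unsupported contour schema version '%s'", p$version %||% "<missing>")
  contours <- lapply(p$contours, function(c)
    contour(c$slice,
            do.call(rbind, lapply(c$vertices, unlist)),
            label = c$label, hole = isTRUE(c$hole)))
  roi_set(contours, spacing = unlist(p$spacing),
          observer_id = p$observer_id, slice_count = p$slice_count)
}

# ---- image sets -------------------------------------------------------

#' Write an acquisition image set as NIfTI + JSON sidecar
#'
#' MOLLI and DWI series are written as one 4-D NIfTI volume plus a
#' sidecar recording the schedule (the sidecar is authoritative); ASL
#' sets are written as three 3-D volumes (label, control, M0) plus the
#' kinetic constants.
#'
#' @param x a `molli_series`, `dwi_series` or `asl_set`.
#' @param dir output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
write_image_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- file.path(dir, "series.json")
  if (inherits(x, "molli_series")) {
    RNifti::writeNifti(RNifti::asNifti(x$frames), file.path(dir, "molli.nii.gz"))
    meta <- list(type = "molli", file = "molli.nii.gz", ti_ms = x$ti_ms,
                 spacing = x$spacing)
  } else if (inherits(x, "dwi_series")) {
    RNifti::writeNifti(RNifti::asNifti(x$frames), file.path(dir, "dwi.nii.gz"))
    meta <- list(type = "dwi", file = "dwi.nii.gz",
                 b_s_per_mm2 = x$b_s_per_mm2, spacing = x$spacing)
  } else if (inherits(x, "asl_set")) {
    RNifti::writeNifti(RNifti::asNifti(x$label_img), file.path(dir, "asl_label.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(x$control_img), file.path(dir, "asl_control.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(x$m0_img), file.path(dir, "asl_m0.nii.gz"))
    meta <- list(type = "asl",
                 files = list(label = "asl_label.nii.gz",
                              control = "asl_control.nii.gz",
                              m0 = "asl_m0.nii.gz"),
                 constants = unclass(x$constants), spacing = x$spacing)
  } else stopf("unsupported image set class '%s'", class(x)[1L])
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an acquisition image set written by [write_image_set()]
#'
#' Validates frame counts against the sidecar schedule: a mismatch
#' between the number of image frames and scheduled TIs/b-values raises
#' an error naming both counts.
#'
#' @param dir directory containing the NIfTI volume(s) and `series.json`.
#' @return A `molli_series`, `dwi_series` or `asl_set`.
#' @export
read_image_set <- function(dir) {
  sidecar <- file.path(dir, "series.json")
  if (!file.exists(sidecar)) stopf("no series.json sidecar in %s", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  spacing <- as.numeric(meta$spacing)
  if (identical(meta$type, "molli")) {
    arr <- as.array(RNifti::readNifti(file.path(dir, meta$file)))
    nfr <- if (length(dim(arr)) == 4L) dim(arr)[4L] else 1L
    if (nfr != length(meta$ti_ms))
      stopf("frame count (%d) does not match TI schedule length (%d)",
            nfr, length(meta$ti_ms))
    structure(list(frames = array(arr, dim = dim(arr)),
                   ti_ms = as.numeric(meta$ti_ms), spacing = spacing),
              class = "molli_series")
  } else if (identical(meta$type, "dwi")) {
    arr <- as.array(RNifti::readNifti(file.path(dir, meta$file)))
    nfr <- if (length(dim(arr)) == 4L) dim(arr)[4L] else 1L
    if (nfr != length(meta$b_s_per_mm2))
      stopf("frame count (%d) does not match b-value schedule length (%d)",
            nfr, length(meta$b_s_per_mm2))
    structure(list(frames = array(arr, dim = dim(arr)),
                   b_s_per_mm2 = as.numeric(meta$b_s_per_mm2),
                   spacing = spacing),
              class = "dwi_series")
  } else if (identical(meta$type, "asl")) {
    imgs <- lapply(meta$files, function(f) {
      a <- RNifti::readNifti(file.path(dir, f))
      array(as.array(a), dim = dim(a))
    })
    cst <- do.call(asl_constants, as.list(meta$constants))
    structure(list(label_img = imgs$label, control_img = imgs$control,
                   m0_img = imgs$m0, constants = cst, spacing = spacing),
              class = "asl_set")
  } else stopf("unknown image set type '%s'", meta$type %||% "<missing>")
}

# ---- study configuration ---------------------------------------------

config_defaults <- function() {
  list(
    n_subjects = 8L,
    groups = NULL,                     # optional per-subject group labels
    shape = c(12L, 64L, 64L),
    spacing = c(4, 1.5, 1.5),
    ti_ms = molli_default_tis(),
    b_values = dwi_default_bvalues(),
    asl = unclass(asl_constants()),
    noise_sd = list(molli = 50, dwi = 25, asl = 2.5),
    observer_jitter_mm = 0.5,
    observer_bias_mm = 0,
    rep_cx_radius_mm = 4,
    sd_divisor = "n",
    cov_pooling = "mean",
    seed = 1L)
}

#' Study configuration for the end-to-end pipeline
#'
#' Holds acquisition schedules, phantom geometry, noise levels, observer
#' model, ROI options and seeds. Unknown fields are rejected; the
#' configuration round-trips losslessly through its JSON representation.
#'
#' @param ... named overrides of the defaults (see Details in the
#'   methods vignette).
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(...) {
  over <- list(...)
  base <- config_defaults()
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(base, over)
  # modifyList drops NULL-valued overrides; keep the optional slot present
  if (!"groups" %in% names(cfg)) cfg["groups"] <- list(NULL)
  cfg <- cfg[names(base)]
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  if (cfg$n_subjects < 1L) stopf("`n_subjects` must be >= 1")
  if (!is.null(cfg$groups) && length(cfg$groups) != cfg$n_subjects)
    stopf("`groups` must have one label per subject")
  do.call(asl_constants, cfg$asl)   # validates constants
  if (!cfg$sd_divisor %in% c("n", "n-1")) stopf("invalid `sd_divisor`")
  if (!cfg$cov_pooling %in% c("mean", "rms")) stopf("invalid `cov_pooling`")
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname study_config
#' @export
read_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(p$noise_sd)) p$noise_sd <- as.list(p$noise_sd)
  if (!is.null(p$asl)) p$asl <- as.list(p$asl)
  do.call(study_config, p)
}
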