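ROI_KINDS <- c("WK", "Cx", "repCx", "supCx", "infCx", "Med")

grid_geometry <- function(grid) {
  if (inherits(grid, "labelmap"))
    list(shape = dim(grid$labels), spacing = grid$spacing)
  else if (is.list(grid) && all(c("shape", "spacing") %in% names(grid)))
    list(shape = as.integer(grid$shape), spacing = as.numeric(grid$spacing))
  else stopf("`grid` must be a labelmap or a list(shape, spacing)")
}

#' Rasterise a contour onto a voxel grid
#'
#' A voxel is included iff its centre lies inside the polygon under the
#' even-odd rule. Hole contours rasterise the same way; callers subtract
#' them (see [rasterize_roi()]).
#'
#' @param c a [contour()].
#' @param grid a `labelmap` or `list(shape, spacing)` defining the grid.
#' @return A logical voxel array (slice, row, col) with the contour's
#'   slice filled.
#' @export
rasterize_contour <- function(c, grid) {
  stopifnot(inherits(c, "contour"))
  g <- grid_geometry(grid)
  nz <- g$shape[1L]; ny <- g$shape[2L]; nx <- g$shape[3L]
  dy <- g$spacing[2L]; dx <- g$spacing[3L]
  if (c$slice < 1L || c$slice > nz)
    stopf("contour slice %d outside grid with %d slices", c$slice, nz)
  v <- c$vertices
  if (any(v[, 1L] < 0) || any(v[, 1L] > nx * dx) ||
      any(v[, 2L] < 0) || any(v[, 2L] > ny * dy))
    stopf("contour extends outside the %g x %g mm in-plane field of view",
          nx * dx, ny * dy)
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  px <- rep(xc, each = ny); py <- rep(yc, times = nx)
  inside <- point_in_polygon(px, py, v)
  mask <- array(FALSE, g$shape)
  mask[c$slice, , ] <- matrix(inside, ny, nx)
  mask
}

#' Rasterise all contours of one ROI kind
#'
#' Union of the non-hole rings minus the union of hole rings.
#'
#' @param rois an [roi_set()].
#' @param grid grid geometry (see [rasterize_contour()]).
#' @param label ROI kind to rasterise.
#' @return Logical voxel array.
#' @export
rasterize_roi <- function(rois, grid, label = "WK") {
  stopifnot(inherits(rois, "roi_set"))
  g <- grid_geometry(grid)
  cs <- Filter(function(c) c$label == label, rois$contours)
  if (!length(cs)) stopf("no contours labelled '%s'", label)
  mask <- array(FALSE, g$shape)
  holes <- array(FALSE, g$shape)
  for (c in cs) {
    m <- rasterize_contour(c, grid)
    if (c$hole) holes <- holes | m else mask <- mask | m
  }
  mask & !holes
}

# circle contour as a regular 64-gon
circle_contour <- function(slice, cx, cy, r_mm, label, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour(slice, cbind(cx + r_mm * cos(th), cy + r_mm * sin(th)), label = label)
}

#' Define the six-region renal ROI taxonomy on one slice
#'
#' Builds contours for the standard renal ROI kinds on a single analysis
#' slice of a phantom label map: whole kidney excluding pelvis (WK),
#' cortex (Cx), the largest connected medullary region (Med), cortex
#' restricted to the superior / inferior third of the kidney's in-slice
#' bounding box (supCx / infCx), and a circular user-defined
#' representative cortex region (repCx) placed at a seeded random
#' location fully inside cortex.
#'
#' @param labelmap phantom label map.
#' @param slice_index analysis slice; default the slice of maximal kidney
#'   cross-sectional area.
#' @param kinds subset of `c("WK","Cx","repCx","supCx","infCx","Med")`.
#' @param seed seed for the repCx placement.
#' @param rep_cx_radius_mm repCx radius in mm (default 4).
#' @return An [roi_set()] with attribute `slice_index`.
#' @export
define_standard_rois <- function(labelmap, slice_index = NULL,
                                 kinds = ROI_KINDS, seed = 1L,
                                 rep_cx_radius_mm = 4) {
  stopifnot(inherits(labelmap, "labelmap"))
  kinds <- match.arg(kinds, ROI_KINDS, several.ok = TRUE)
  lab <- labelmap$labels
  dy <- labelmap$spacing[2L]; dx <- labelmap$spacing[3L]
  if (is.null(slice_index)) {
    counts <- apply(lab == 1L | lab == 2L, 1L, sum)
    slice_index <- which.max(counts)
  }
  sl <- lab[slice_index, , ]
  if (!any(sl == 1L | sl == 2L))
    stopf("slice %d contains no kidney tissue", slice_index)

  masks <- list()
  if ("WK" %in% kinds) masks$WK <- sl == 1L | sl == 2L
  if ("Cx" %in% kinds || any(c("supCx", "infCx", "repCx") %in% kinds))
    cx <- sl == 1L
  if ("Cx" %in% kinds) masks$Cx <- cx
  if ("Med" %in% kinds) {
    med <- sl == 2L
    cc <- EBImage::bwlabel(med * 1)
    if (max(cc) > 0L) {
      sizes <- tabulate(cc[cc > 0])
      med <- cc == which.max(sizes)
    }
    masks$Med <- med
  }
  if (any(c("supCx", "infCx") %in% kinds)) {
    kid <- sl == 1L | sl == 2L
    rows <- which(apply(kid, 1L, any))
    r0 <- min(rows); r1 <- max(rows)
    third <- (r1 - r0 + 1L) / 3
    if ("supCx" %in% kinds) {
      m <- cx; m[seq_len(nrow(m)) > r0 + third - 1L, ] <- FALSE
      masks$supCx <- m
    }
    if ("infCx" %in% kinds) {
      m <- cx; m[seq_len(nrow(m)) < r1 - third + 1L, ] <- FALSE
      masks$infCx <- m
    }
  }

  contours <- list()
  for (nm in names(masks)) {
    if (!any(masks[[nm]]))
      stopf("ROI '%s' is empty on slice %d", nm, slice_index)
    rings <- mask_slice_contours(masks[[nm]], dy, dx)
    for (r in rings)
      contours[[length(contours) + 1L]] <-
        contour(slice_index, r$vertices, label = nm, hole = r$hole)
  }

  if ("repCx" %in% kinds) {
    # candidate centres: cortex pixels whose inscribed disc stays in cortex
    dmap <- EBImage::distmap(cx * 1) * min(dy, dx)
    cand <- which(cx & dmap > rep_cx_radius_mm, arr.ind = TRUE)
    if (nrow(cand) == 0L)
      stopf("cortex too thin for a repCx radius of %g mm; use a smaller radius",
            rep_cx_radius_mm)
    pick <- with_seed(seed, cand[sample.int(nrow(cand), 1L), ])
    cxmm <- (pick[2L] - 0.5) * dx
    cymm <- (pick[1L] - 0.5) * dy
    contours[[length(contours) + 1L]] <-
      circle_contour(slice_index, cxmm, cymm, rep_cx_radius_mm, "repCx")
  }

  out <- roi_set(contours, spacing = labelmap$spacing,
                 observer_id = "auto", slice_count = dim(lab)[1L])
  attr(out, "slice_index") <- as.integer(slice_index)
  out
}

#' Summary statistics of a parameter map over a voxel mask
#'
#' Mean, within-ROI standard deviation (population divisor n by default,
#' mirroring typical imaging-software ROI statistics; configurable to
#' n - 1), voxel count, and the SD expressed as a fraction of the mean.
#'
#' @param map a [parameter_map()].
#' @param mask logical voxel array.
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return An object of class `roi_summary` with elements `mean`, `sd`,
#'   `n_voxels`, `sd_fraction`, `units`.
#' @export
roi_summary <- function(map, mask, sd_divisor = c("n", "n-1")) {
  stopifnot(inherits(map, "parameter_map"))
  sd_divisor <- match.arg(sd_divisor)
  stopifnot(identical(dim(mask), dim(map$values)))
  v <- map$values[mask & map$mask]
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 1L) stopf("mask contains no finite map voxels")
  m <- mean(v)
  s <- if (n == 1L) 0 else stats::sd(v) * if (sd_divisor == "n")
    sqrt((n - 1) / n) else 1
  structure(list(mean = m, sd = s, n_voxels = n,
                 sd_fraction = if (m != 0) s / m else NA_real_,
                 units = map$units),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> mean %.4g %s, SD %.4g (%.1f%% of mean), n = %d\n",
              x$mean, x$units, x$sd,
              100 * (x$sd_fraction %||% NA_real_), x$n_voxels))
  invisible(x)
}

#' Corticomedullary ratio
#'
#' Ratio of the cortical to the medullary ROI mean, the standard index of
#' corticomedullary differentiation.
#'
#' @param cx,med `roi_summary` objects (or bare numeric means).
#' @return `cx$mean / med$mean`.
#' @export
cortex_medulla_ratio <- function(cx, med) {
  mc <- if (inherits(cx, "roi_summary")) cx$mean else as.numeric(cx)
  mm <- if (inherits(med, "roi_summary")) med$mean else as.numeric(med)
  if (!is.finite(mm) || mm == 0) stopf("medullary mean is zero or undefined")
  mc / mm
}

#' Within-ROI spread as a proportion of the mean, across subjects
#'
#' For each sequence x ROI kind: the mean of the within-ROI SDs across
#' subjects, and that mean SD as a percentage of the mean of the subject
#' means (reported to 1 decimal place).
#'
#' @param summaries data frame / tibble with columns `subject`,
#'   `roi_kind`, `mean`, `sd`, `units`, and optionally `sequence`.
#' @return Tibble with `sequence` (if present), `roi_kind`,
#'   `mean_roi_sd`, `sd_fraction_pct`.
#' @export
sd_fraction_report <- function(summaries) {
  summaries <- as.data.frame(summaries)
  need <- c("subject", "roi_kind", "mean", "sd", "units")
  if (!all(need %in% names(summaries)))
    stopf("`summaries` must have columns %s", paste(need, collapse = ", "))
  if (nrow(summaries) < 1L) stopf("need at least one subject")
  grp_cols <- intersect(c("sequence", "roi_kind"), names(summaries))
  key <- interaction(summaries[grp_cols], drop = TRUE)
  rows <- lapply(split(summaries, key), function(d) {
    if (length(unique(d$units)) != 1L)
      stopf("unit mismatch across subjects for ROI '%s'", d$roi_kind[1L])
    mean_sd <- mean(d$sd)
    mean_val <- mean(d$mean)
    out <- d[1L, grp_cols, drop = FALSE]
    out$mean_roi_sd <- mean_sd
    out$sd_fraction_pct <- round(100 * mean_sd / mean_val, 1L)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  tibble::as_tibble(res)
}
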