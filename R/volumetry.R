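# Net cross-sectional area (outer rings minus holes) per contoured slice.
slice_area_table <- function(rois, label = NULL) {
  cs <- rois$contours
  if (!is.null(label)) cs <- Filter(function(c) c$label == label, cs)
  if (!length(cs)) stopf("no contours%s in the ROI set",
                         if (is.null(label)) "" else sprintf(" labelled '%s'", label))
  slices <- vapply(cs, `[[`, 1L, "slice")
  areas <- vapply(cs, function(c)
    (if (c$hole) -1 else 1) * contour_area(c), 1)
  agg <- tapply(areas, slices, sum)
  out <- data.frame(slice = as.integer(names(agg)), area_mm2 = as.numeric(agg))
  if (any(out$area_mm2 < 0))
    stopf("hole area exceeds outer contour area on slice %d",
          out$slice[which(out$area_mm2 < 0)[1L]])
  out[order(out$slice), , drop = FALSE]
}

#' Kidney volume from contours on every slice
#'
#' Sums the net contoured cross-sectional area on each slice between the
#' first and last contoured slice, multiplied by the slice spacing.
#' Every intermediate slice must carry a contour.
#'
#' @param rois an [roi_set()]; spacing element 1 (dz) is the slice spacing
#'   used for integration.
#' @param label ROI kind to integrate (default "WK").
#' @return Volume in ml (1 ml = 1000 mm^3).
#' @export
volume_every_slice <- function(rois, label = "WK") {
  stopifnot(inherits(rois, "roi_set"))
  tab <- slice_area_table(rois, label)
  full <- seq.int(min(tab$slice), max(tab$slice))
  missing <- setdiff(full, tab$slice)
  if (length(missing))
    stopf("every-slice protocol violated: slice %d has no contour", missing[1L])
  sum(tab$area_mm2) * rois$spacing[1L] / 1000
}

#' Kidney volume from contours on alternate slices
#'
#' Implements the alternate-slice protocol: contours are required on the
#' first and last slices containing kidney and on every alternate slice
#' between; the cross-sectional areas of the non-contoured slices are
#' linearly interpolated from the flanking contoured slices before
#' integrating area x slice spacing.
#'
#' @inheritParams volume_every_slice
#' @return Volume in ml.
#' @export
volume_alternate_slice <- function(rois, label = "WK") {
  stopifnot(inherits(rois, "roi_set"))
  tab <- slice_area_table(rois, label)
  s <- tab$slice
  gaps <- diff(s)
  if (any(gaps > 2L))
    stopf("alternate-slice protocol violated: %d consecutive slices missing after slice %d",
          gaps[which(gaps > 2L)[1L]] - 1L, s[which(gaps > 2L)[1L]])
  full <- seq.int(min(s), max(s))
  area <- stats::approx(s, tab$area_mm2, xout = full, method = "linear")$y
  sum(area) * rois$spacing[1L] / 1000
}
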