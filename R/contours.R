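#' Planar contour on an image slice
#'
#' A closed polygon drawn on one slice of an image stack, with in-plane
#' vertex coordinates in millimetres. The polygon is implicitly closed
#' (an edge joins the last vertex back to the first). Contours flagged as
#' holes subtract from the region enclosed by their parent ring, which is
#' how a whole-kidney region excluding the renal pelvis is represented.
#'
#' @param slice 1-based slice index the contour lives on.
#' @param vertices numeric matrix with columns (x, y) in mm; at least three
#'   rows; must describe a simple (non-self-intersecting) polygon.
#' @param label ROI kind the contour belongs to (e.g. "WK", "Cx").
#' @param hole logical; `TRUE` marks a subtractive ring.
#' @return An object of class `contour`.
#' @export
contour <- function(slice, vertices, label = "WK", hole = FALSE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stopf("`vertices` must be a numeric matrix with columns (x, y)")
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (n > 1L && all(vertices[1L, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L)
    stopf("a contour needs at least 3 distinct vertices, got %d", nrow(vertices))
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stopf("contour vertices must be finite")
  if (!is_simple_polygon(vertices))
    stopf("contour on slice %d is self-intersecting", slice)
  structure(
    list(slice = as.integer(slice), vertices = unname(vertices),
         label = as.character(label), hole = isTRUE(hole)),
    class = "contour")
}

#' Set of contours for one observer
#'
#' @param contours list of [contour()] objects.
#' @param spacing voxel spacing in mm, ordered like the image dimensions
#'   (slice, row, column) = (dz, dy, dx).
#' @param observer_id identifier of the (real or simulated) observer.
#' @param slice_count number of slices in the parent image stack.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(contours, spacing, observer_id = "obs", slice_count = NULL) {
  if (!is.list(contours) || !all(vapply(contours, inherits, TRUE, "contour")))
    stopf("`contours` must be a list of contour objects")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be three positive numbers (dz, dy, dx)")
  slices <- vapply(contours, `[[`, 1L, "slice")
  slice_count <- as.integer(slice_count %||% if (length(slices)) max(slices) else 0L)
  if (length(slices) && (any(slices < 1L) || any(slices > slice_count)))
    stopf("contour slice indices must lie in 1..%d", slice_count)
  structure(
    list(contours = contours, spacing = spacing,
         observer_id = as.character(observer_id), slice_count = slice_count),
    class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> observer '%s': %d contour(s) on %d slice(s), spacing (%g, %g, %g) mm\n",
              x$observer_id, length(x$contours),
              length(unique(vapply(x$contours, `[[`, 1L, "slice"))),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# ---- polygon primitives -----------------------------------------------

signed_polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area enclosed by a contour
#'
#' Absolute shoelace area of the polygon, independent of vertex orientation.
#'
#' @param c a [contour()].
#' @return Area in mm^2.
#' @export
contour_area <- function(c) {
  if (!inherits(c, "contour")) stopf("`c` must be a contour")
  abs(signed_polygon_area(c$vertices))
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Points exactly on an edge may fall on either side; callers relying on
# exact boundary behaviour should avoid placing vertices on voxel centres.
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

# O(n^2) segment-intersection simplicity check (proper crossings only;
# shared endpoints of adjacent edges are allowed).
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- seq_len(n)
  p1 <- v; p2 <- v[c(idx[-1L], 1L), , drop = FALSE]
  seg_orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    js <- seq.int(i + 1L, n)
    # skip edges sharing a vertex with edge i
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    o1 <- seg_orient(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[js, 1], p1[js, 2])
    o2 <- seg_orient(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[js, 1], p2[js, 2])
    o3 <- seg_orient(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2],
                     rep(p1[i, 1], length(js)), rep(p1[i, 2], length(js)))
    o4 <- seg_orient(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2],
                     rep(p2[i, 1], length(js)), rep(p2[i, 2], length(js)))
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0))
      return(FALSE)
  }
  TRUE
}

# Outward unit normals at each vertex (mean of adjacent edge normals).
vertex_outward_normals <- function(v) {
  n <- nrow(v)
  nxt <- v[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  prv <- v[c(n, seq_len(n)[-n]), , drop = FALSE]
  t <- nxt - prv                      # central-difference tangent
  len <- sqrt(rowSums(t^2))
  len[len == 0] <- 1
  t <- t / len
  nrm <- cbind(t[, 2L], -t[, 1L])     # right-hand perpendicular
  if (signed_polygon_area(v) < 0) nrm <- -nrm  # ensure outward for CW rings
  nrm
}

# ---- contour extraction from voxel masks ------------------------------

# Marching-squares extraction of the 0.5 iso-contour of a binary slice
# mask (rows x cols), in mm coordinates of voxel centres. Returns a list
# of vertex matrices; rings nested at odd depth are reported as holes.
mask_slice_contours <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  # pad with zeros so contours around objects touching the border close
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(m)
  ycoord <- (seq_len(nr + 2L) - 1.5) * dy   # padded row centres
  xcoord <- (seq_len(nc + 2L) - 1.5) * dx
  cls <- grDevices::contourLines(ycoord, xcoord, z, levels = 0.5)
  rings <- lapply(cls, function(cl) {
    v <- cbind(x = cl$y, y = cl$x)
    n <- nrow(v)
    if (n > 1L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
    v
  })
  rings <- rings[vapply(rings, nrow, 1L) >= 3L]
  if (!length(rings)) return(list())
  depth <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1L, ]
    sum(vapply(seq_along(rings), function(j) {
      j != i && point_in_polygon(p[1L], p[2L], rings[[j]])
    }, TRUE))
  }, 1L)
  lapply(seq_along(rings), function(i)
    list(vertices = rings[[i]], hole = depth[i] %% 2L == 1L))
}

#' Extract contours of labelled compartments from a label map
#'
#' Traces the 0.5 iso-contour of the union of the requested labels on each
#' slice (marching squares on the voxel-centre grid), producing per-slice
#' polygons suitable for volumetry and ROI statistics. Interior cavities
#' (e.g. the renal pelvis excluded from a whole-kidney region) come out as
#' hole-flagged rings.
#'
#' @param labelmap a [make_kidney_labelmap()] result (or compatible object).
#' @param labels integer labels whose union is contoured (default cortex +
#'   medulla, i.e. whole kidney excluding pelvis).
#' @param roi_label ROI kind recorded on each contour.
#' @param slices slice indices to contour; default all slices containing
#'   any of the requested labels.
#' @param observer_id observer identifier stored on the returned set.
#' @return An [roi_set()].
#' @export
labelmap_contours <- function(labelmap, labels = c(1L, 2L), roi_label = "WK",
                              slices = NULL, observer_id = "truth") {
  stopifnot(inherits(labelmap, "labelmap"))
  dims <- dim(labelmap$labels)
  dz <- labelmap$spacing[1L]; dy <- labelmap$spacing[2L]; dx <- labelmap$spacing[3L]
  member <- array(labelmap$labels %in% labels, dim = dims)
  if (is.null(slices))
    slices <- which(apply(member, 1L, any))
  out <- list()
  for (s in slices) {
    rings <- mask_slice_contours(member[s, , ], dy, dx)
    for (r in rings)
      out[[length(out) + 1L]] <- contour(s, r$vertices, label = roi_label,
                                         hole = r$hole)
  }
  roi_set(out, spacing = labelmap$spacing, observer_id = observer_id,
          slice_count = dims[1L])
}
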