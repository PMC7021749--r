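#' Default MOLLI inversion-time schedule (ms)
#'
#' Fourteen inversion times of the 11(3)3 MOLLI scheme used for native and
#' transplant kidneys: initial delays of 180 and 260 ms with 550 ms
#' increments between subsequent measurements.
#' @return Numeric vector of inversion times in ms.
#' @export
molli_default_tis <- function() {
  c(180, 260, 730, 810, 1280, 1360, 1830, 2380, 2930, 3480, 4030, 4580, 5130, 5680)
}

#' Default diffusion-weighting schedule (s/mm^2)
#'
#' Ten b-values spanning 0 to 1000 s/mm^2 for mono-exponential ADC fitting.
#' @return Numeric vector of b-values.
#' @export
dwi_default_bvalues <- function() {
  c(0, 50, 100, 150, 200, 250, 300, 500, 750, 1000)
}

#' Synthetic coronal kidney label map
#'
#' Builds a single-kidney digital phantom on a (slice, row, column) voxel
#' grid: an ellipsoidal kidney whose outer shell is cortex (label 1),
#' whose interior carries wedge-shaped medullary pyramids (label 2)
#' separated by cortical columns, and whose centre holds an interior
#' renal-pelvis region (label 3). Cross-sectional area varies smoothly
#' across slices and at least one slice at each stack end is free of
#' kidney tissue. Geometry is mildly randomised (centre, semi-axes, wedge
#' phase) so different seeds give different kidneys.
#'
#' @param shape grid dimensions (slices, rows, columns); at least (8, 32, 32).
#' @param spacing voxel size in mm ordered like `shape`: (dz, dy, dx).
#' @param seed integer seed; output is deterministic given the seed.
#' @return An object of class `labelmap`: integer label array plus spacing.
#' @export
make_kidney_labelmap <- function(shape = c(12L, 64L, 64L),
                                 spacing = c(4, 1.5, 1.5),
                                 seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < c(8L, 32L, 32L)))
    stopf("`shape` must be (slices, rows, cols) with at least (8, 32, 32)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be three positive voxel sizes in mm")
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  Lz <- nz * spacing[1L]; Ly <- ny * spacing[2L]; Lx <- nx * spacing[3L]

  geo <- with_seed(seed, list(
    cz = Lz / 2 + runif(1, -0.25, 0.25) * spacing[1L],
    cy = Ly / 2 + runif(1, -0.5, 0.5) * spacing[2L],
    cx = Lx / 2 + runif(1, -0.5, 0.5) * spacing[3L],
    az = 0.32 * Lz * runif(1, 0.96, 1.04),
    ay = 0.40 * Ly * runif(1, 0.95, 1.05),
    ax = 0.25 * Lx * runif(1, 0.95, 1.05),
    phase = runif(1, 0, 2 * pi)))

  zc <- (seq_len(nz) - 0.5) * spacing[1L]
  yc <- (seq_len(ny) - 0.5) * spacing[2L]
  xc <- (seq_len(nx) - 0.5) * spacing[3L]
  Z <- array(rep(zc, times = ny * nx), dim = shape)
  Y <- array(rep(rep(yc, each = nz), times = nx), dim = shape)
  X <- array(rep(xc, each = nz * ny), dim = shape)

  rz <- (Z - geo$cz) / geo$az
  ry <- (Y - geo$cy) / geo$ay
  rx <- (X - geo$cx) / geo$ax
  r2 <- rz^2 + ry^2 + rx^2
  outer_in <- r2 <= 1
  inner_in <- r2 <= 0.62^2

  # interior pelvis: small ellipsoid offset towards the medial (x) side
  pz <- (Z - geo$cz) / (0.45 * geo$az)
  py <- (Y - geo$cy) / (0.26 * geo$ay)
  px <- (X - (geo$cx + 0.22 * geo$ax)) / (0.24 * geo$ax)
  pelvis <- inner_in & (pz^2 + py^2 + px^2 <= 1)

  # wedge-shaped medullary pyramids separated by cortical columns
  theta <- atan2((Y - geo$cy) / geo$ay, (X - geo$cx) / geo$ax)
  wedge <- cos(6 * theta + geo$phase) > -0.25

  labels <- array(0L, dim = shape)
  labels[outer_in] <- 1L                     # cortex shell (and columns)
  labels[inner_in & wedge] <- 2L             # medulla
  labels[pelvis] <- 3L                       # renal pelvis

  kidney_slices <- which(apply(labels > 0L, 1L, any))
  if (length(kidney_slices) == 0L ||
      min(kidney_slices) <= 1L || max(kidney_slices) >= nz)
    stopf("phantom geometry reached the stack ends; enlarge `shape`")

  structure(list(labels = labels, spacing = spacing,
                 compartments = c(background = 0L, cortex = 1L,
                                  medulla = 2L, pelvis = 3L)),
            class = "labelmap")
}

#' @export
print.labelmap <- function(x, ...) {
  d <- dim(x$labels)
  counts <- table(factor(x$labels, levels = 0:3,
                         labels = names(x$compartments)))
  cat(sprintf("<labelmap> %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  print(counts)
  invisible(x)
}

#' Ground-truth tissue parameters per phantom compartment
#'
#' Defaults are representative of human kidney at 3 T: medullary T1 above
#' cortical T1, cortical perfusion above medullary perfusion, near-equal
#' cortical/medullary ADC, and a fluid-like pelvis (long T1, free
#' diffusion, negligible perfusion).
#'
#' @param cortex,medulla,pelvis named lists with elements `t1_ms`,
#'   `adc_mm2_per_s`, `perfusion_ml_per_100g_min`, `m0`; all positive.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(
    cortex  = list(t1_ms = 1630, adc_mm2_per_s = 1.68e-3,
                   perfusion_ml_per_100g_min = 221, m0 = 1000),
    medulla = list(t1_ms = 1976, adc_mm2_per_s = 1.67e-3,
                   perfusion_ml_per_100g_min = 96, m0 = 1000),
    pelvis  = list(t1_ms = 3200, adc_mm2_per_s = 3.0e-3,
                   perfusion_ml_per_100g_min = 1, m0 = 1000)) {
  comp <- list(cortex = cortex, medulla = medulla, pelvis = pelvis)
  need <- c("t1_ms", "adc_mm2_per_s", "perfusion_ml_per_100g_min", "m0")
  for (nm in names(comp)) {
    vals <- comp[[nm]]
    if (!all(need %in% names(vals)))
      stopf("compartment '%s' must supply %s", nm, paste(need, collapse = ", "))
    for (f in need) {
      v <- vals[[f]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stopf("tissue parameter %s of '%s' must be a single finite number", f, nm)
      # perfusion may be exactly zero (avascular fluid); the rest must be positive
      if (v < 0 || (v == 0 && f != "perfusion_ml_per_100g_min"))
        stopf("tissue parameter %s of '%s' must be positive", f, nm)
    }
  }
  structure(comp, class = "tissue_params")
}

# Expand a per-compartment tissue field into a voxel array (0 outside).
compartment_field <- function(labelmap, params, field) {
  lut <- c(0,
           params$cortex[[field]],
           params$medulla[[field]],
           params$pelvis[[field]])
  array(lut[labelmap$labels + 1L], dim = dim(labelmap$labels))
}

add_noise <- function(x, noise_sd, noise_model = "gaussian") {
  if (noise_sd == 0) return(x)
  if (noise_model == "gaussian") {
    x + array(rnorm(length(x), 0, noise_sd), dim = dim(x))
  } else if (noise_model == "rician") {
    re <- x + array(rnorm(length(x), 0, noise_sd), dim = dim(x))
    im <- array(rnorm(length(x), 0, noise_sd), dim = dim(x))
    sqrt(re^2 + im^2)
  } else stopf("unknown noise model '%s'", noise_model)
}

#' Simulate a MOLLI inversion-recovery series
#'
#' Generates signed (phase-sensitive-like) inversion-recovery signal
#' `S(TI) = A - B exp(-TI / T1*)` with `A = m0`, `B = 2 m0 beta` per
#' compartment, where `beta` is the inversion efficiency (default 1, so
#' the apparent `T1*` equals the ground-truth T1), plus Gaussian noise.
#'
#' @param labelmap phantom label map.
#' @param params [tissue_params()].
#' @param ti_ms strictly increasing positive inversion times (ms).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param beta inversion efficiency in (0.5, 1]; `T1* = T1 / (2 beta - 1)`.
#' @param seed RNG seed.
#' @return A `molli_series`: 4-D signal array (slice, row, col, TI) plus
#'   the TI schedule and spacing.
#' @export
simulate_molli_series <- function(labelmap, params, ti_ms = molli_default_tis(),
                                  noise_sd = 50, beta = 1, seed = 1L) {
  stopifnot(inherits(labelmap, "labelmap"), inherits(params, "tissue_params"))
  ti_ms <- as.numeric(ti_ms)
  if (length(ti_ms) < 3L || any(ti_ms <= 0) || any(diff(ti_ms) <= 0))
    stopf("`ti_ms` must be at least 3 strictly increasing positive times")
  if (beta <= 0.5 || beta > 1) stopf("`beta` must lie in (0.5, 1]")
  m0 <- compartment_field(labelmap, params, "m0")
  t1 <- compartment_field(labelmap, params, "t1_ms")
  t1s <- t1 / (2 * beta - 1)
  dims <- dim(labelmap$labels)
  frames <- array(0, dim = c(dims, length(ti_ms)))
  for (i in seq_along(ti_ms)) {
    s <- m0
    inside <- t1s > 0
    s[inside] <- m0[inside] - 2 * beta * m0[inside] * exp(-ti_ms[i] / t1s[inside])
    frames[, , , i] <- s
  }
  frames <- with_seed(seed, add_noise(frames, noise_sd))
  structure(list(frames = frames, ti_ms = ti_ms, spacing = labelmap$spacing),
            class = "molli_series")
}

#' Simulate a multi-b diffusion-weighted series
#'
#' Mono-exponential decay `S(b) = S0 exp(-b ADC)` with `S0 = m0`, plus
#' Gaussian (default) or Rician noise.
#'
#' @inheritParams simulate_molli_series
#' @param b_values non-negative b-values in s/mm^2; must include 0.
#' @param noise_model "gaussian" (signed) or "rician" (magnitude).
#' @return A `dwi_series`: 4-D array (slice, row, col, b) plus schedule.
#' @export
simulate_dwi_series <- function(labelmap, params, b_values = dwi_default_bvalues(),
                                noise_sd = 25, noise_model = c("gaussian", "rician"),
                                seed = 1L) {
  stopifnot(inherits(labelmap, "labelmap"), inherits(params, "tissue_params"))
  noise_model <- match.arg(noise_model)
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L || any(b_values < 0))
    stopf("`b_values` must be at least two non-negative values")
  if (!any(b_values == 0))
    stopf("`b_values` must include b = 0 (S0 anchoring)")
  m0 <- compartment_field(labelmap, params, "m0")
  adc <- compartment_field(labelmap, params, "adc_mm2_per_s")
  dims <- dim(labelmap$labels)
  frames <- array(0, dim = c(dims, length(b_values)))
  for (i in seq_along(b_values))
    frames[, , , i] <- m0 * exp(-b_values[i] * adc)
  frames <- with_seed(seed, add_noise(frames, noise_sd, noise_model))
  structure(list(frames = frames, b_s_per_mm2 = b_values,
                 spacing = labelmap$spacing),
            class = "dwi_series")
}

#' Simulate a pCASL label/control/M0 set
#'
#' The control image is the proton-density baseline `M0`; the label image
#' is `control - deltaM`, where `deltaM` is computed from the ground-truth
#' perfusion by [forward_asl_signal()]. Noise is added independently to
#' label and control; the stored M0 image is noiseless.
#'
#' @inheritParams simulate_molli_series
#' @param constants an [asl_constants()] object.
#' @return An `asl_set` with `label_img`, `control_img`, `m0_img`,
#'   `constants` and `spacing`.
#' @export
simulate_asl_set <- function(labelmap, params, constants = asl_constants(),
                             noise_sd = 2.5, seed = 1L) {
  stopifnot(inherits(labelmap, "labelmap"), inherits(params, "tissue_params"),
            inherits(constants, "asl_constants"))
  m0 <- compartment_field(labelmap, params, "m0")
  f <- compartment_field(labelmap, params, "perfusion_ml_per_100g_min")
  dm <- forward_asl_signal(f, m0, constants)
  set <- with_seed(seed, list(
    label_img = add_noise(m0 - dm, noise_sd),
    control_img = add_noise(m0, noise_sd)))
  structure(list(label_img = set$label_img, control_img = set$control_img,
                 m0_img = m0, constants = constants,
                 spacing = labelmap$spacing),
            class = "asl_set")
}

#' Simulated observer model for contour variability
#'
#' Describes how a second human observer re-draws contours: a systematic
#' over/under-contouring bias plus zero-mean jitter along the local
#' outward normal. With zero jitter and zero bias the observer reproduces
#' the input exactly.
#'
#' @param boundary_jitter_mm non-negative SD of vertex displacement (mm).
#' @param bias_mm signed systematic displacement (mm); positive enlarges
#'   regions (holes shrink accordingly).
#' @param seed RNG seed; perturbation is deterministic per seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(boundary_jitter_mm = 0.5, bias_mm = 0, seed = 1L) {
  assert_scalar_number(boundary_jitter_mm, "boundary_jitter_mm")
  if (boundary_jitter_mm < 0) stopf("`boundary_jitter_mm` must be >= 0")
  assert_scalar_number(bias_mm, "bias_mm")
  structure(list(boundary_jitter_mm = boundary_jitter_mm,
                 bias_mm = bias_mm, seed = as.integer(seed)),
            class = "observer_model")
}

# Smooth per-vertex Gaussian jitter along a closed ring so neighbouring
# vertices move coherently (as a human hand would), rescaled to keep the
# marginal SD equal to jitter_mm.
correlated_ring_noise <- function(n, jitter_mm) {
  if (jitter_mm == 0) return(numeric(n))
  g <- rnorm(n)
  k <- c(1, 2, 3, 2, 1)
  k <- k / sqrt(sum(k^2))           # unit-variance circular smoothing
  idx <- outer(seq_len(n), -2:2, function(i, o) ((i + o - 1L) %% n) + 1L)
  sm <- as.vector(matrix(g[idx], n, 5L) %*% k)
  jitter_mm * sm
}

#' Apply a simulated observer to a contour set
#'
#' Each vertex is displaced along the local outward normal by
#' `bias_mm + N(0, jitter_mm)` with spatially correlated jitter; hole
#' rings move in the opposite sense so a positive bias enlarges the
#' enclosed region. Draws that self-intersect are redrawn from the next
#' substream (deterministically) until simple.
#'
#' @param rois an [roi_set()].
#' @param model an [observer_model()].
#' @return A new [roi_set()] with the model's seed-tagged observer id.
#' @export
perturb_contours <- function(rois, model) {
  stopifnot(inherits(rois, "roi_set"), inherits(model, "observer_model"))
  out <- with_seed(model$seed, {
    lapply(rois$contours, function(cn) {
      v <- cn$vertices
      nrm <- vertex_outward_normals(v)
      sgn <- if (cn$hole) -1 else 1
      for (attempt in 1:25) {
        d <- model$bias_mm * sgn +
          sgn * correlated_ring_noise(nrow(v), model$boundary_jitter_mm)
        v2 <- v + d * nrm
        if (model$boundary_jitter_mm == 0 && model$bias_mm == 0) {
          v2 <- v  # exact identity, immune to floating-point 0 * x
        }
        if (is_simple_polygon(v2))
          return(contour(cn$slice, v2, label = cn$label, hole = cn$hole))
      }
      stopf("could not produce a simple perturbed contour on slice %d", cn$slice)
    })
  })
  roi_set(out, spacing = rois$spacing,
          observer_id = sprintf("sim-observer-%d", model$seed),
          slice_count = rois$slice_count)
}
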