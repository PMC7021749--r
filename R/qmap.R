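#' Kinetic constants for pCASL perfusion quantification
#'
#' Constants of the single-compartment pCASL model. Defaults: labelling
#' start-to-imaging time t = 3000 ms, label duration tau = 1500 ms,
#' arterial transit time 750 ms, labelling efficiency 0.98, blood-tissue
#' water partition coefficient 0.9 ml/g, and fixed
#' `T1blood = T1' = 1250 ms`. The partition coefficient is interpreted in
#' ml/g (the conventional unit); see the methods vignette.
#'
#' @param t_ms time between start of labelling and imaging (ms).
#' @param tau_ms labelling duration (ms).
#' @param delta_t_ms arterial transit time (ms).
#' @param alpha labelling efficiency in (0, 1].
#' @param lambda_ml_per_g blood-tissue water partition coefficient (ml/g).
#' @param t1_blood_ms longitudinal relaxation time of arterial blood (ms).
#' @param t1_app_ms apparent tissue longitudinal relaxation time T1' (ms).
#' @return An object of class `asl_constants`.
#' @export
asl_constants <- function(t_ms = 3000, tau_ms = 1500, delta_t_ms = 750,
                          alpha = 0.98, lambda_ml_per_g = 0.9,
                          t1_blood_ms = 1250, t1_app_ms = 1250) {
  for (nm in c("t_ms", "tau_ms", "delta_t_ms", "alpha", "lambda_ml_per_g",
               "t1_blood_ms", "t1_app_ms"))
    assert_scalar_number(get(nm), nm, positive = TRUE)
  if (alpha > 1) stopf("`alpha` must lie in (0, 1]")
  if (t_ms < tau_ms + delta_t_ms)
    stopf("`t_ms` must be >= tau_ms + delta_t_ms (got %g < %g + %g)",
          t_ms, tau_ms, delta_t_ms)
  structure(list(t_ms = t_ms, tau_ms = tau_ms, delta_t_ms = delta_t_ms,
                 alpha = alpha, lambda_ml_per_g = lambda_ml_per_g,
                 t1_blood_ms = t1_blood_ms, t1_app_ms = t1_app_ms),
            class = "asl_constants")
}

# Dimensionless kinetic factor multiplying (f_SI * m0): deltaM =
# f_SI * m0 * asl_kinetic_factor(c), with f_SI in ml g^-1 ms^-1.
asl_kinetic_factor <- function(c) {
  (2 / c$lambda_ml_per_g) * c$t1_app_ms * c$alpha *
    exp(-c$delta_t_ms / c$t1_blood_ms) *
    exp(-(c$t_ms - c$tau_ms - c$delta_t_ms) / c$t1_app_ms) *
    (1 - exp(-c$tau_ms / c$t1_app_ms))
}

# conversion: ml/100 g/min -> ml/g/ms
PERF_TO_SI <- 1 / (100 * 60000)

#' Forward pCASL signal model
#'
#' Evaluates the label/control difference signal
#' `deltaM = f (2 M0 / lambda) T1' alpha exp(-dt/T1blood)
#'  exp(-(t - tau - dt)/T1') (1 - exp(-tau/T1'))`
#' for perfusion `f` given in ml/100 g/min (converted internally to
#' ml g^-1 ms^-1). Linear in both `f` and `m0`.
#'
#' @param f perfusion in ml/100 g/min (scalar or array); must be >= 0.
#' @param m0 proton-density signal (scalar or array, recycled).
#' @param c an [asl_constants()] object.
#' @return deltaM in the units of `m0`.
#' @export
forward_asl_signal <- function(f, m0, c = asl_constants()) {
  stopifnot(inherits(c, "asl_constants"))
  if (any(f < 0)) stopf("perfusion `f` must be non-negative")
  f * PERF_TO_SI * m0 * asl_kinetic_factor(c)
}

#' Per-voxel quantitative parameter map
#'
#' @param values numeric voxel array.
#' @param units one of "ms", "mm^2/s", "ml/100 g/min" (or another unit
#'   string applied at the reporting layer).
#' @param mask logical array of analysed voxels; values are finite only
#'   within the mask.
#' @param quality per-voxel fit diagnostic (RMS residual), same shape.
#' @param flags integer per-voxel status: 0 ok, 1 non-converged,
#'   2 boundary/degenerate, 3 invalid input.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, units, mask = NULL, quality = NULL,
                          flags = NULL) {
  values <- as.array(values)
  if (is.null(mask)) mask <- array(is.finite(values), dim = dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  values[!mask] <- NA_real_
  structure(list(values = values, units = as.character(units),
                 mask = mask,
                 quality = quality %||% array(NA_real_, dim = dim(values)),
                 flags = flags %||% array(0L, dim = dim(values))),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$mask & is.finite(x$values)]
  cat(sprintf("<parameter_map> [%s] %s voxels in mask; median %.4g (IQR %.4g-%.4g)\n",
              x$units, format(sum(x$mask)), stats::median(v),
              stats::quantile(v, 0.25), stats::quantile(v, 0.75)))
  invisible(x)
}

# ---- shared Levenberg-Marquardt machinery -----------------------------

# Vectorised LM for separable exponential models; `update` returns a list
# with residual matrix R (V x T) and Jacobian columns (list of V x T
# matrices or length-V vectors) for the CURRENT parameter matrix P (V x p).
# Iterates until relative SSE change < tol for every active voxel.
lm_polish <- function(P, model_fun, lower, upper, tol = 1e-12, max_iter = 200L) {
  V <- nrow(P); p <- ncol(P)
  mu <- rep(1e-3, V)
  ev <- model_fun(P)
  sse <- rowSums(ev$R^2)
  converged <- rep(FALSE, V)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    act <- which(!converged)
    if (!length(act)) break
    J <- ev$J
    # normal-equation components on active voxels
    if (p == 2L) {
      a11 <- rowSums(J[[1L]]^2); a12 <- rowSums(J[[1L]] * J[[2L]])
      a22 <- rowSums(J[[2L]]^2)
      g1 <- rowSums(J[[1L]] * ev$R); g2 <- rowSums(J[[2L]] * ev$R)
      d11 <- a11 * (1 + mu); d22 <- a22 * (1 + mu)
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- NA_real_
      s1 <- (d22 * g1 - a12 * g2) / det
      s2 <- (d11 * g2 - a12 * g1) / det
      step <- cbind(s1, s2)
    } else {
      a11 <- rowSums(J[[1L]]^2); a12 <- rowSums(J[[1L]] * J[[2L]])
      a13 <- rowSums(J[[1L]] * J[[3L]]); a22 <- rowSums(J[[2L]]^2)
      a23 <- rowSums(J[[2L]] * J[[3L]]); a33 <- rowSums(J[[3L]]^2)
      g1 <- rowSums(J[[1L]] * ev$R); g2 <- rowSums(J[[2L]] * ev$R)
      g3 <- rowSums(J[[3L]] * ev$R)
      d11 <- a11 * (1 + mu); d22 <- a22 * (1 + mu); d33 <- a33 * (1 + mu)
      C11 <- d22 * d33 - a23^2; C12 <- a13 * a23 - a12 * d33
      C13 <- a12 * a23 - a13 * d22
      C22 <- d11 * d33 - a13^2; C23 <- a12 * a13 - d11 * a23
      C33 <- d11 * d22 - a12^2
      det <- d11 * C11 + a12 * C12 + a13 * C13
      det[abs(det) < 1e-300] <- NA_real_
      s1 <- (C11 * g1 + C12 * g2 + C13 * g3) / det
      s2 <- (C12 * g1 + C22 * g2 + C23 * g3) / det
      s3 <- (C13 * g1 + C23 * g2 + C33 * g3) / det
      step <- cbind(s1, s2, s3)
    }
    step[!is.finite(step)] <- 0
    cand <- P + step
    # box constraints: reject out-of-bound candidates (treated as failed step)
    ok_box <- rep(TRUE, V)
    for (j in seq_len(p))
      ok_box <- ok_box & cand[, j] > lower[j] & cand[, j] < upper[j]
    cand[!ok_box, ] <- P[!ok_box, , drop = FALSE]
    ev_cand <- model_fun(cand)
    sse_cand <- rowSums(ev_cand$R^2)
    better <- ok_box & is.finite(sse_cand) & sse_cand <= sse
    improve <- better & !converged
    # convergence on accepted steps with negligible SSE change
    newly <- improve & (sse - sse_cand) <= tol * (sse + 1e-300)
    P[improve, ] <- cand[improve, , drop = FALSE]
    sse[improve] <- sse_cand[improve]
    mu[improve] <- pmax(mu[improve] / 3, 1e-12)
    fail <- !better & !converged
    mu[fail] <- pmin(mu[fail] * 10, 1e10)
    # a voxel whose damping has exploded has stalled; stop moving it
    newly <- newly | (fail & mu >= 1e10)
    converged <- converged | newly
    ev <- model_fun(P)
  }
  list(P = P, sse = sse, converged = converged, iterations = iter)
}

# ---- T1 fitting -------------------------------------------------------

# Variable-projection initialisation + LM polish for the three-parameter
# inversion-recovery model S = A - B exp(-TI / T1star) on a V x T matrix.
t1_fit_core <- function(S, ti, n_grid = 80L, t1s_range = c(50, 10000)) {
  V <- nrow(S); T <- length(ti)
  grid <- exp(seq(log(t1s_range[1L]), log(t1s_range[2L]), length.out = n_grid))
  ss_raw <- rowSums(S^2)
  s_sum <- rowSums(S)
  best_sse <- rep(Inf, V); best <- matrix(NA_real_, V, 3L)
  for (g in grid) {
    E <- exp(-ti / g)
    Se <- sum(E); See <- sum(E^2)
    det <- T * See - Se^2
    sE <- as.vector(S %*% E)
    A <- (s_sum * See - Se * sE) / det
    B <- (Se * s_sum - T * sE) / det
    sse <- pmax(ss_raw - (A * s_sum - B * sE), 0)
    take <- sse < best_sse & A > 0 & B > 0
    if (any(take)) {
      best_sse[take] <- sse[take]
      best[take, 1L] <- A[take]; best[take, 2L] <- B[take]
      best[take, 3L] <- g
    }
  }
  usable <- is.finite(best[, 1L])
  fitted <- matrix(NA_real_, V, 3L)
  conv <- rep(FALSE, V)
  if (any(usable)) {
    Su <- S[usable, , drop = FALSE]
    model_fun <- function(P) {
      E <- exp(-outer(1 / P[, 3L], ti))
      R <- Su - (P[, 1L] - P[, 2L] * E)
      J3 <- -(P[, 2L] / P[, 3L]^2) * E * rep(ti, each = nrow(P))
      list(R = R, J = list(matrix(1, nrow(P), length(ti)), -E, J3))
    }
    res <- lm_polish(best[usable, , drop = FALSE], model_fun,
                     lower = c(0, 0, 1), upper = c(Inf, Inf, 50000))
    fitted[usable, ] <- res$P
    conv[usable] <- res$converged
    best_sse[usable] <- res$sse
  }
  list(A = fitted[, 1L], B = fitted[, 2L], t1star = fitted[, 3L],
       sse = best_sse, converged = conv, usable = usable)
}

#' Fit a T1 map from a MOLLI series
#'
#' Per-voxel least-squares fit of the signed three-parameter
#' inversion-recovery model `S(TI) = A - B exp(-TI / T1*)` with
#' `A, B, T1* > 0`, followed by the Look-Locker correction
#' `T1 = T1* (B/A - 1)`. Initial values come from a variable-projection
#' scan over `T1*` (linear solve for A, B at each candidate); a
#' Levenberg-Marquardt polish then iterates to an SSE change below 1e-12
#' (at most 200 iterations). Voxels that fail (all-zero series,
#' non-convergence, violated positivity) are flagged and set non-finite,
#' never raised as errors.
#'
#' @param series a `molli_series` (signed, phase-sensitive-like data).
#' @param mask logical voxel array to fit; default: voxels with any
#'   nonzero signal.
#' @return A [parameter_map()] in ms, with RMS residual as quality and
#'   per-voxel status flags.
#' @export
fit_t1_map <- function(series, mask = NULL) {
  stopifnot(inherits(series, "molli_series"))
  dims <- dim(series$frames)[1:3]
  flat <- matrix(series$frames, prod(dims), length(series$ti_ms))
  if (is.null(mask))
    mask <- array(rowSums(abs(flat)) > 0, dim = dims)
  stopifnot(identical(dim(mask), dims))
  idx <- which(as.vector(mask))
  values <- array(NA_real_, dims)
  quality <- array(NA_real_, dims)
  flags <- array(0L, dims)
  if (length(idx)) {
    S <- flat[idx, , drop = FALSE]
    degen <- apply(S, 1L, function(r) all(r == r[1L]))
    fit <- t1_fit_core(S[!degen, , drop = FALSE], series$ti_ms)
    t1 <- rep(NA_real_, length(idx)); rmse <- rep(NA_real_, length(idx))
    fl <- rep(0L, length(idx))
    fl[degen] <- 3L
    sub <- which(!degen)
    t1[sub] <- fit$t1star * (fit$B / fit$A - 1)
    rmse[sub] <- sqrt(fit$sse / length(series$ti_ms))
    fl[sub[!fit$usable]] <- 2L
    fl[sub[fit$usable & !fit$converged]] <- 1L
    bad_val <- !is.na(t1[sub]) & t1[sub] <= 0
    fl[sub[bad_val]] <- 2L
    t1[sub][bad_val] <- NA_real_
    t1[fl > 0L] <- NA_real_
    values[idx] <- t1
    quality[idx] <- rmse
    flags[idx] <- fl
  }
  parameter_map(values, units = "ms", mask = mask, quality = quality,
                flags = flags)
}

# ---- ADC fitting ------------------------------------------------------

adc_fit_core <- function(S, b, adc_max = 0.05) {
  V <- nrow(S)
  eps <- 1e-12
  pos <- S > 0
  npos <- rowSums(pos)
  usable <- npos >= 2L
  P0 <- matrix(NA_real_, V, 2L)
  if (any(usable)) {
    # log-linear initialisation on positive signals
    lS <- log(pmax(S, eps))
    w <- pos * 1
    sw <- rowSums(w); sb <- as.vector(w %*% b); sbb <- as.vector(w %*% b^2)
    sy <- rowSums(w * lS); sby <- rowSums(w * lS * rep(b, each = V))
    det <- sw * sbb - sb^2
    slope <- (sw * sby - sb * sy) / det
    icpt <- (sy - slope * sb) / sw
    adc0 <- pmin(pmax(-slope, 0), adc_max * 0.99)
    s00 <- exp(icpt)
    P0[, 1L] <- s00; P0[, 2L] <- adc0
  }
  fitted <- matrix(NA_real_, V, 2L); conv <- rep(FALSE, V)
  sse <- rep(NA_real_, V)
  if (any(usable)) {
    Su <- S[usable, , drop = FALSE]
    model_fun <- function(P) {
      E <- exp(-outer(P[, 2L], b))
      f <- P[, 1L] * E
      list(R = Su - f, J = list(E, -f * rep(b, each = nrow(P))))
    }
    res <- lm_polish(P0[usable, , drop = FALSE], model_fun,
                     lower = c(0, -1e-15), upper = c(Inf, adc_max))
    fitted[usable, ] <- res$P
    conv[usable] <- res$converged
    sse[usable] <- res$sse
  }
  list(s0 = fitted[, 1L], adc = fitted[, 2L], sse = sse,
       converged = conv, usable = usable)
}

#' Fit an ADC map from a multi-b diffusion series
#'
#' Per-voxel nonlinear least squares of the mono-exponential model
#' `S(b) = S0 exp(-b ADC)` with `S0 > 0, ADC >= 0`: log-linear regression
#' on the positive signals initialises (S0, ADC), then a
#' Levenberg-Marquardt polish refines to an SSE change below 1e-12. The
#' map is stored in mm^2/s; the conventional reporting scale of
#' 1e-6 mm^2/s is applied only at the reporting layer. Voxels with
#' non-positive signal at every b are flagged invalid; voxels pinned at
#' the ADC = 0 boundary (e.g. constant signal) are flagged as boundary
#' fits but keep the value 0.
#'
#' @param series a `dwi_series`.
#' @param mask logical voxel array; default voxels with any positive signal.
#' @return A [parameter_map()] in mm^2/s.
#' @export
fit_adc_map <- function(series, mask = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  dims <- dim(series$frames)[1:3]
  b <- series$b_s_per_mm2
  if (length(unique(b)) < 2L) stopf("need at least two distinct b-values")
  flat <- matrix(series$frames, prod(dims), length(b))
  if (is.null(mask))
    mask <- array(rowSums(flat > 0) > 0, dim = dims)
  stopifnot(identical(dim(mask), dims))
  idx <- which(as.vector(mask))
  values <- array(NA_real_, dims); quality <- array(NA_real_, dims)
  flags <- array(0L, dims)
  if (length(idx)) {
    S <- flat[idx, , drop = FALSE]
    fit <- adc_fit_core(S, b)
    adc <- fit$adc
    fl <- rep(0L, length(idx))
    fl[!fit$usable] <- 3L
    fl[fit$usable & !fit$converged] <- 1L
    boundary <- fit$usable & is.finite(adc) & adc <= 1e-12
    adc[boundary] <- 0
    fl[boundary] <- 2L
    adc[fl == 1L | fl == 3L] <- NA_real_
    values[idx] <- adc
    quality[idx] <- sqrt(fit$sse / length(b))
    flags[idx] <- fl
  }
  parameter_map(values, units = "mm^2/s", mask = mask, quality = quality,
                flags = flags)
}

# ---- perfusion --------------------------------------------------------

#' Compute a perfusion map from a pCASL set
#'
#' Inverts the forward pCASL model voxel-wise:
#' `deltaM = control - label`, then
#' `f = deltaM * lambda / (2 M0 T1' alpha exp(-dt/T1blood)
#'  exp(-(t-tau-dt)/T1') (1 - exp(-tau/T1')))`,
#' rescaled to ml/100 g/min. Negative perfusion values (possible under
#' noise) are preserved, not clipped; their fraction is reported in the
#' map's `negative_fraction` attribute. Voxels whose M0 falls below
#' `m0_floor` are flagged and set non-finite.
#'
#' @param asl an `asl_set`.
#' @param mask logical voxel array; default voxels with `M0 > m0_floor`.
#' @param m0_floor minimum admissible M0 signal.
#' @return A [parameter_map()] in ml/100 g/min.
#' @export
perfusion_map <- function(asl, mask = NULL, m0_floor = 1e-6) {
  stopifnot(inherits(asl, "asl_set"))
  dims <- dim(asl$m0_img)
  if (!identical(dim(asl$label_img), dims) ||
      !identical(dim(asl$control_img), dims))
    stopf("label/control/M0 grids do not match")
  if (is.null(mask)) mask <- array(asl$m0_img > m0_floor, dim = dims)
  stopifnot(identical(dim(mask), dims))
  dm <- asl$control_img - asl$label_img
  k <- asl_kinetic_factor(asl$constants)
  values <- array(NA_real_, dims)
  flags <- array(0L, dims)
  low <- mask & asl$m0_img <= m0_floor
  ok <- mask & !low
  values[ok] <- dm[ok] / (asl$m0_img[ok] * k) / PERF_TO_SI
  flags[low] <- 3L
  neg_frac <- if (any(ok)) mean(values[ok] < 0) else NA_real_
  pm <- parameter_map(values, units = "ml/100 g/min", mask = mask,
                      quality = array(0, dims), flags = flags)
  attr(pm, "negative_fraction") <- neg_frac
  pm
}
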