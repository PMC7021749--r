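# Independent oracles and shared small fixtures for the test suite.

# Small phantom reused across unit tests (the acceptance tests use the
# full default geometry).
test_lm <- make_kidney_labelmap(shape = c(8, 32, 32), spacing = c(4, 2, 2),
                                seed = 7)
test_pars <- tissue_params()

# Brute-force dense grid search over (A, B, T1*) minimising SSE of the
# three-parameter inversion-recovery model, with three refinement rounds.
# Independent of the fitter's variable-projection path.
oracle_t1_grid <- function(s, ti, rounds = 4L) {
  smax <- max(abs(s))
  lo <- c(0.2 * smax, 0.2 * smax, 100)
  hi <- c(2.0 * smax, 4.0 * smax, 6000)
  best <- NULL
  for (r in seq_len(rounds)) {
    Ag <- seq(lo[1], hi[1], length.out = 21)
    Bg <- seq(lo[2], hi[2], length.out = 21)
    Tg <- seq(lo[3], hi[3], length.out = 31)
    cand <- as.matrix(expand.grid(A = Ag, B = Bg, T = Tg))
    pred <- matrix(cand[, "A"], nrow(cand), length(ti)) -
      cand[, "B"] * exp(-outer(1 / cand[, "T"], ti))
    sse <- rowSums((pred - matrix(s, nrow(cand), length(ti), byrow = TRUE))^2)
    best <- cand[which.min(sse), ]
    span <- (hi - lo) / c(10, 10, 15)
    lo <- pmax(best - span, c(1e-6, 1e-6, 1))
    hi <- best + span
  }
  t1 <- best["T"] * (best["B"] / best["A"] - 1)
  unname(c(A = best["A"], B = best["B"], t1star = best["T"], t1 = t1))
}

# Log-linear regression oracle for mono-exponential diffusion decay
# (exact on noiseless data).
oracle_adc_loglin <- function(s, b) {
  fit <- stats::lm(log(s) ~ b)
  c(s0 = exp(unname(coef(fit)[1])), adc = -unname(coef(fit)[2]))
}

# Two-way ANOVA mean squares by explicit double loops.
oracle_icc_loops <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + x[i, j]
  grand <- grand / (n * k)
  mi <- numeric(n); cj <- numeric(k)
  for (i in 1:n) { for (j in 1:k) mi[i] <- mi[i] + x[i, j]; mi[i] <- mi[i] / k }
  for (j in 1:k) { for (i in 1:n) cj[j] <- cj[j] + x[i, j]; cj[j] <- cj[j] / n }
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in 1:n) ssr <- ssr + (mi[i] - grand)^2
  for (j in 1:k) ssc <- ssc + (cj[j] - grand)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - mi[i] - cj[j] + grand)^2
  MSR <- k * ssr / (n - 1); MSC <- n * ssc / (k - 1)
  MSE <- sse / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (MSC - MSE) / n)
}

# Independent mean-squares route through stats::aov.
oracle_icc_aov <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(value = as.vector(x),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = d))[[1]]
  MSR <- tab["subject", "Mean Sq"]; MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (MSC - MSE) / n)
}

# Build a single-voxel MOLLI series from closed-form signal values.
voxel_molli <- function(signal, ti, spacing = c(4, 2, 2)) {
  structure(list(frames = array(signal, dim = c(1, 1, 1, length(ti))),
                 ti_ms = ti, spacing = spacing),
            class = "molli_series")
}

voxel_dwi <- function(signal, b, spacing = c(4, 2, 2)) {
  structure(list(frames = array(signal, dim = c(1, 1, 1, length(b))),
                 b_s_per_mm2 = b, spacing = spacing),
            class = "dwi_series")
}
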