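test_that("T1 fitting recovers the three-parameter model with Look-Locker correction", {
  ti <- molli_default_tis()
  # B = 2A makes the apparent and corrected T1 coincide
  s <- 100 - 200 * exp(-ti / 800)
  fit <- fit_t1_map(voxel_molli(s, ti))
  expect_equal(fit$values[1, 1, 1], 800, tolerance = 1e-6)
  expect_identical(fit$units, "ms")
  # B != 2A exercises the correction: T1 = T1* (B/A - 1)
  s2 <- 100 - 180 * exp(-ti / 900)
  fit2 <- fit_t1_map(voxel_molli(s2, ti))
  expect_equal(fit2$values[1, 1, 1], 900 * (180 / 100 - 1), tolerance = 1e-6)
  # all-zero voxel is flagged, not an error
  fit0 <- fit_t1_map(voxel_molli(rep(0, length(ti)), ti),
                     mask = array(TRUE, c(1, 1, 1)))
  expect_true(is.na(fit0$values[1, 1, 1]))
  expect_identical(fit0$flags[1, 1, 1], 3L)
})

test_that("noiseless phantom T1 round-trip stays under 0.5% in every compartment", {
  mol <- simulate_molli_series(test_lm, test_pars, noise_sd = 0)
  fit <- fit_t1_map(mol)
  truth <- c(test_pars$cortex$t1_ms, test_pars$medulla$t1_ms,
             test_pars$pelvis$t1_ms)
  for (comp in 1:3) {
    v <- fit$values[test_lm$labels == comp]
    expect_lt(max(abs(v / truth[comp] - 1)), 0.005)
  }
})

test_that("T1 fit matches the dense grid-search oracle and tolerates noise", {
  ti <- molli_default_tis()
  set.seed(31)
  # ten random noiseless voxels: parameter agreement with grid search < 0.1%
  for (i in 1:10) {
    A <- runif(1, 400, 1500); B <- runif(1, 1.6, 2.4) * A
    t1s <- runif(1, 600, 2200)
    s <- A - B * exp(-ti / t1s)
    mine <- fit_t1_map(voxel_molli(s, ti))$values[1, 1, 1]
    orc <- oracle_t1_grid(s, ti)[4]
    expect_lt(abs(mine / orc - 1), 0.001)
    expect_lt(abs(mine / (t1s * (B / A - 1)) - 1), 1e-6)
  }
  # 500 replicate noisy voxels at 2% of A: median |error| < 3%
  A <- 1000; B <- 2000; t1 <- 1400
  set.seed(77)
  errs <- replicate(500, {
    s <- A - B * exp(-ti / t1) + rnorm(length(ti), 0, 0.02 * A)
    fit_t1_map(voxel_molli(s, ti))$values[1, 1, 1] / t1 - 1
  })
  expect_lt(median(abs(errs)), 0.03)
})

test_that("ADC fitting: exact two-point solution, boundary flag, oracle agreement", {
  fit <- fit_adc_map(voxel_dwi(c(1000, 1000 * exp(-1.7)), c(0, 1000)))
  expect_equal(fit$values[1, 1, 1] * 1e6, 1700, tolerance = 1e-6)
  expect_identical(fit$units, "mm^2/s")
  # constant signal pins ADC at the zero boundary, flagged not dropped
  fitc <- fit_adc_map(voxel_dwi(rep(500, 10), dwi_default_bvalues()))
  expect_identical(fitc$values[1, 1, 1], 0)
  expect_identical(fitc$flags[1, 1, 1], 2L)
  # non-positive signal everywhere -> invalid flag
  fitn <- fit_adc_map(voxel_dwi(rep(-5, 10), dwi_default_bvalues()),
                      mask = array(TRUE, c(1, 1, 1)))
  expect_true(is.na(fitn$values[1, 1, 1]))
  expect_identical(fitn$flags[1, 1, 1], 3L)
  # ten random noiseless voxels vs log-linear oracle
  b <- dwi_default_bvalues()
  set.seed(13)
  for (i in 1:10) {
    s0 <- runif(1, 300, 1500); adc <- runif(1, 0.8e-3, 2.8e-3)
    s <- s0 * exp(-b * adc)
    mine <- fit_adc_map(voxel_dwi(s, b))$values[1, 1, 1]
    orc <- oracle_adc_loglin(s, b)["adc"]
    expect_lt(abs(mine / orc - 1), 0.001)
    expect_lt(abs(mine / adc - 1), 1e-6)
  }
})

test_that("noiseless phantom ADC round-trip error is below 1e-6 relative", {
  dw <- simulate_dwi_series(test_lm, test_pars, noise_sd = 0)
  fit <- fit_adc_map(dw)
  truth <- c(test_pars$cortex$adc_mm2_per_s, test_pars$medulla$adc_mm2_per_s,
             test_pars$pelvis$adc_mm2_per_s)
  for (comp in 1:3) {
    v <- fit$values[test_lm$labels == comp]
    expect_lt(max(abs(v / truth[comp] - 1)), 1e-6)
  }
})

test_that("forward ASL signal evaluates the kinetic model exactly and is linear in f", {
  # frozen from an independent high-precision evaluation of the model at
  # defaults with f = 200 ml/100 g/min, m0 = 1
  expect_equal(forward_asl_signal(200, 1), 0.0190987716158, tolerance = 1e-9)
  expect_identical(forward_asl_signal(0, 1), 0)
  f <- c(10, 50, 123.4)
  expect_equal(forward_asl_signal(2 * f, 1), 2 * forward_asl_signal(f, 1))
  expect_equal(forward_asl_signal(100, 7), 7 * forward_asl_signal(100, 1))
  expect_error(forward_asl_signal(-1, 1), "non-negative")
  expect_error(asl_constants(alpha = 1.2), "alpha")
  expect_error(asl_constants(t_ms = 2000, tau_ms = 1500, delta_t_ms = 750),
               "t_ms")
})

test_that("perfusion map inverts the forward model", {
  pars <- tissue_params(cortex = list(t1_ms = 1600, adc_mm2_per_s = 1.7e-3,
                                      perfusion_ml_per_100g_min = 250, m0 = 1000))
  asl <- simulate_asl_set(test_lm, pars, noise_sd = 0)
  pm <- perfusion_map(asl)
  cx <- test_lm$labels == 1L
  expect_lt(max(abs(pm$values[cx] / 250 - 1)), 1e-6)
  expect_identical(pm$units, "ml/100 g/min")
  # control == label -> f = 0 everywhere
  asl0 <- asl; asl0$label_img <- asl0$control_img
  pm0 <- perfusion_map(asl0)
  expect_true(all(pm0$values[pm0$mask] == 0))
  # doubling M0 at fixed deltaM halves f
  asl2 <- asl; asl2$m0_img <- 2 * asl$m0_img
  pm2 <- perfusion_map(asl2)
  expect_equal(pm2$values[cx], pm$values[cx] / 2)
  # mismatched grids rejected
  aslbad <- asl; aslbad$label_img <- asl$label_img[, 1:10, , drop = FALSE]
  expect_error(perfusion_map(aslbad), "grid")
  # inverse-forward composition is the identity for any valid constants
  set.seed(6)
  for (i in 1:5) {
    cst <- asl_constants(t_ms = runif(1, 2500, 4000), tau_ms = runif(1, 800, 1600),
                         delta_t_ms = runif(1, 400, 900), alpha = runif(1, 0.8, 1),
                         lambda_ml_per_g = runif(1, 0.8, 1),
                         t1_blood_ms = runif(1, 1100, 1700),
                         t1_app_ms = runif(1, 1000, 1600))
    f <- runif(1, 20, 400); m0 <- runif(1, 500, 2000)
    aslc <- structure(list(label_img = array(m0 - forward_asl_signal(f, m0, cst), c(1, 1, 1)),
                           control_img = array(m0, c(1, 1, 1)),
                           m0_img = array(m0, c(1, 1, 1)),
                           constants = cst, spacing = c(4, 2, 2)),
                      class = "asl_set")
    expect_lt(abs(perfusion_map(aslc)$values[1, 1, 1] / f - 1), 1e-6)
  }
})

test_that("perfusion estimate is unbiased under noise and flags negatives", {
  cst <- asl_constants()
  n <- 1e4
  m0 <- rep(1000, n)
  dm_true <- forward_asl_signal(200, m0, cst)
  set.seed(5)
  noise_sd <- 10   # 1% of the control signal
  asl <- structure(list(
    label_img = array(m0 - dm_true + rnorm(n, 0, noise_sd), c(1, 1, n)),
    control_img = array(m0 + rnorm(n, 0, noise_sd), c(1, 1, n)),
    m0_img = array(m0, c(1, 1, n)),
    constants = cst, spacing = c(4, 2, 2)), class = "asl_set")
  pm <- perfusion_map(asl)
  expect_lt(abs(mean(pm$values) / 200 - 1), 0.02)
  expect_gt(attr(pm, "negative_fraction"), 0)   # noise produces some negatives
  expect_true(all(is.finite(pm$values)))        # negatives preserved, not NA
})
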