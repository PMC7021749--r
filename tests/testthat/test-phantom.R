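test_that("label map is deterministic, seed-sensitive, and anatomically consistent", {
  a <- make_kidney_labelmap(shape = c(12, 64, 64), spacing = c(4, 1.5, 1.5), seed = 7)
  b <- make_kidney_labelmap(shape = c(12, 64, 64), spacing = c(4, 1.5, 1.5), seed = 7)
  c <- make_kidney_labelmap(shape = c(12, 64, 64), spacing = c(4, 1.5, 1.5), seed = 8)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
  expect_true(all(a$labels %in% 0:3))
  # every slice holding medulla also holds cortex (shell topology)
  med_slices <- which(apply(a$labels == 2L, 1, any))
  cx_slices <- which(apply(a$labels == 1L, 1, any))
  expect_true(all(med_slices %in% cx_slices))
  # kidney-free slices at both stack ends
  kid <- apply(a$labels > 0L, 1, any)
  expect_false(kid[1]); expect_false(kid[length(kid)])
  # cross-sectional area varies smoothly (unimodal up-down profile)
  areas <- apply(array(a$labels %in% 1:2, dim(a$labels)), 1, sum)
  areas <- areas[areas > 0]
  expect_lte(sum(diff(sign(diff(areas))) != 0), 2)
  expect_error(make_kidney_labelmap(shape = c(4, 64, 64)), "at least")
  expect_error(make_kidney_labelmap(spacing = c(0, 1, 1)), "positive")
})

test_that("inversion-recovery signal crosses zero at TI = T1 ln 2 and validates its schedule", {
  pars <- tissue_params(cortex = list(t1_ms = 1600, adc_mm2_per_s = 1.7e-3,
                                      perfusion_ml_per_100g_min = 200, m0 = 1000))
  tis <- sort(c(100, 1600 * log(2), 3000, 5000))
  mol <- simulate_molli_series(test_lm, pars, ti_ms = tis, noise_sd = 0)
  zi <- which(tis == 1600 * log(2))
  cx <- test_lm$labels == 1L
  sig <- mol$frames[, , , zi][cx]
  expect_lt(max(abs(sig)), 1e-9)
  # short-TI signal is negative (signed polarity preserved)
  expect_true(all(mol$frames[, , , 1][cx] < 0))
  # default schedule accepted and stored in metadata
  mol2 <- simulate_molli_series(test_lm, test_pars, noise_sd = 0)
  expect_identical(mol2$ti_ms,
                   c(180, 260, 730, 810, 1280, 1360, 1830, 2380, 2930,
                     3480, 4030, 4580, 5130, 5680))
  expect_error(simulate_molli_series(test_lm, test_pars, ti_ms = c(300, 200, 500)),
               "increasing")
})

test_that("diffusion decay matches its closed form and requires b = 0", {
  pars <- tissue_params(cortex = list(t1_ms = 1600, adc_mm2_per_s = 1.7e-3,
                                      perfusion_ml_per_100g_min = 200, m0 = 1000))
  dw <- simulate_dwi_series(test_lm, pars, b_values = c(0, 1000), noise_sd = 0)
  cx <- test_lm$labels == 1L
  ratio <- dw$frames[, , , 2][cx] / dw$frames[, , , 1][cx]
  expect_equal(unique(round(ratio, 12)), round(exp(-1.7), 12))
  dw2 <- simulate_dwi_series(test_lm, test_pars, noise_sd = 0)
  expect_identical(dw2$b_s_per_mm2,
                   c(0, 50, 100, 150, 200, 250, 300, 500, 750, 1000))
  expect_error(simulate_dwi_series(test_lm, test_pars, b_values = c(50, 1000)),
               "b = 0")
})

test_that("simulated noise level is calibrated on background voxels", {
  big_lm <- make_kidney_labelmap(seed = 2)   # default grid: >1e4 background voxels
  mol <- simulate_molli_series(big_lm, test_pars, noise_sd = 50, seed = 42)
  bg <- big_lm$labels == 0L
  expect_gte(sum(bg), 1e4)
  emp <- sd(mol$frames[, , , 1][bg])
  expect_lt(abs(emp / 50 - 1), 0.05)
  # rician option produces non-negative magnitude data
  dw <- simulate_dwi_series(big_lm, test_pars, noise_sd = 25,
                            noise_model = "rician", seed = 1)
  expect_true(all(dw$frames >= 0))
})

test_that("asl set equals control exactly for zero perfusion and rejects negative f", {
  pars0 <- tissue_params(
    cortex = list(t1_ms = 1600, adc_mm2_per_s = 1.7e-3,
                  perfusion_ml_per_100g_min = 0, m0 = 1000),
    medulla = list(t1_ms = 1900, adc_mm2_per_s = 1.6e-3,
                   perfusion_ml_per_100g_min = 0, m0 = 1000),
    pelvis = list(t1_ms = 3200, adc_mm2_per_s = 3e-3,
                  perfusion_ml_per_100g_min = 0, m0 = 1000))
  asl <- simulate_asl_set(test_lm, pars0, noise_sd = 0)
  expect_identical(asl$label_img, asl$control_img)
  expect_error(tissue_params(cortex = list(t1_ms = 1600, adc_mm2_per_s = 1.7e-3,
                                           perfusion_ml_per_100g_min = -5, m0 = 1000)),
               "positive")
  # default constants carry the assumed acquisition values
  cst <- asl_constants()
  expect_identical(c(cst$t_ms, cst$tau_ms, cst$delta_t_ms, cst$alpha,
                     cst$lambda_ml_per_g, cst$t1_blood_ms, cst$t1_app_ms),
                   c(3000, 1500, 750, 0.98, 0.9, 1250, 1250))
})

test_that("observer perturbation: identity at zero, exact ring-area growth, seed sensitivity", {
  wk <- labelmap_contours(test_lm)
  id <- perturb_contours(wk, observer_model(0, 0, seed = 3))
  expect_identical(lapply(id$contours, `[[`, "vertices"),
                   lapply(wk$contours, `[[`, "vertices"))
  # +1 mm bias on a radius-20 circle adds the exact ring area 2*pi*r*t + pi*t^2
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- contour(2, cbind(40 + 20 * cos(th), 40 + 20 * sin(th)))
  cs <- roi_set(list(circ), c(4, 1.5, 1.5), "t", 8)
  grown <- perturb_contours(cs, observer_model(0, bias_mm = 1, seed = 1))
  d_area <- contour_area(grown$contours[[1]]) - contour_area(circ)
  expect_lt(abs(d_area / (2 * pi * 20 * 1 + pi * 1^2) - 1), 0.005)
  # a hole ring shrinks under positive bias (region grows)
  hole <- contour(2, cbind(40 + 5 * cos(th), 40 + 5 * sin(th)), hole = TRUE)
  hs <- roi_set(list(hole), c(4, 1.5, 1.5), "t", 8)
  shrunk <- perturb_contours(hs, observer_model(0, bias_mm = 1, seed = 1))
  expect_lt(contour_area(shrunk$contours[[1]]), contour_area(hole))
  p1 <- perturb_contours(wk, observer_model(0.5, 0, seed = 1))
  p2 <- perturb_contours(wk, observer_model(0.5, 0, seed = 2))
  expect_false(identical(lapply(p1$contours, `[[`, "vertices"),
                         lapply(p2$contours, `[[`, "vertices")))
  # determinism of the perturbation itself
  p1b <- perturb_contours(wk, observer_model(0.5, 0, seed = 1))
  expect_identical(lapply(p1$contours, `[[`, "vertices"),
                   lapply(p1b$contours, `[[`, "vertices"))
})

test_that("two simulated observers agree on whole-kidney volume within 5%", {
  lm <- make_kidney_labelmap(seed = 5)
  wk <- labelmap_contours(lm)
  va <- volume_every_slice(perturb_contours(wk, observer_model(0.5, 0, seed = 11)))
  vb <- volume_every_slice(perturb_contours(wk, observer_model(0.5, 0, seed = 12)))
  expect_lt(abs(va - vb) / mean(c(va, vb)), 0.05)
})
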