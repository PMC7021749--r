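test_that("rasterisation follows the voxel-centre even-odd rule with holes", {
  geom <- list(shape = c(4, 8, 8), spacing = c(4, 1, 1))
  # square enclosing exactly a 3x3 block of voxel centres (at 1.5, 2.5, 3.5)
  sq <- contour(2, rbind(c(1.2, 1.2), c(4.2, 1.2), c(4.2, 4.2), c(1.2, 4.2)))
  m <- rasterize_contour(sq, geom)
  expect_identical(sum(m), 9L)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] == 2L))
  # hole equal to the outer ring empties the mask
  hole <- contour(2, sq$vertices, hole = TRUE)
  rs <- roi_set(list(sq, hole), spacing = geom$spacing, observer_id = "t",
                slice_count = 4)
  expect_identical(sum(rasterize_roi(rs, geom, "WK")), 0L)
  # circle radius 10 mm on a 1 mm grid: count within 3% of pi r^2
  geom2 <- list(shape = c(3, 32, 32), spacing = c(4, 1, 1))
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- contour(1, cbind(16 + 10 * cos(th), 16 + 10 * sin(th)))
  expect_lt(abs(sum(rasterize_contour(circ, geom2)) / (pi * 100) - 1), 0.03)
  expect_error(rasterize_contour(contour(9, sq$vertices), geom), "slice")
  far <- contour(2, rbind(c(-5, 0), c(5, 0), c(0, 5)))
  expect_error(rasterize_contour(far, geom), "field of view")
})

test_that("even-odd point-in-polygon test agrees with mgcv::in.out", {
  skip_if_not_installed("mgcv")
  set.seed(4)
  th <- sort(runif(12, 0, 2 * pi))
  v <- cbind(5 + (2 + runif(12)) * cos(th), 5 + (2 + runif(12)) * sin(th))
  px <- runif(500, 0, 10); py <- runif(500, 0, 10)
  mine <- renalqmap:::point_in_polygon(px, py, v)
  ref <- mgcv::in.out(rbind(v, v[1, ]), cbind(px, py))
  expect_identical(mine, as.vector(ref))
})

test_that("standard ROI taxonomy satisfies its mask algebra", {
  rois <- define_standard_rois(test_lm, seed = 3)
  sl <- attr(rois, "slice_index")
  masks <- lapply(setNames(nm = c("WK", "Cx", "repCx", "supCx", "infCx", "Med")),
                  function(k) rasterize_roi(rois, test_lm, k))
  # WK equals cortex + medulla on the analysis slice (pelvis excluded)
  lab_sl <- test_lm$labels[sl, , ]
  expect_identical(masks$WK[sl, , ], lab_sl == 1L | lab_sl == 2L)
  expect_identical(masks$Cx[sl, , ], lab_sl == 1L)
  expect_true(all(masks$WK[masks$Cx | masks$Med]))
  expect_true(all(masks$Cx[masks$repCx]))
  expect_true(all(masks$Cx[masks$supCx]))
  expect_true(all(masks$Cx[masks$infCx]))
  expect_identical(sum(masks$supCx & masks$infCx), 0L)
  # medulla ROI is one connected medullary region
  expect_true(all(test_lm$labels[masks$Med] == 2L))
  # repCx placement is seed-dependent but always inside cortex
  r2 <- define_standard_rois(test_lm, seed = 9, kinds = "repCx")
  m2 <- rasterize_roi(r2, test_lm, "repCx")
  expect_false(identical(which(masks$repCx), which(m2)))
  expect_true(all(test_lm$labels[m2] == 1L))
  expect_error(define_standard_rois(test_lm, seed = 1, rep_cx_radius_mm = 30),
               "smaller radius")
})

test_that("roi_summary computes closed-form statistics with both SD conventions", {
  vals <- array(NA_real_, c(2, 2, 2))
  vals[1, , ] <- 1600
  pmap <- parameter_map(vals, "ms")
  mask <- array(FALSE, c(2, 2, 2)); mask[1, , ] <- TRUE
  s <- roi_summary(pmap, mask)
  expect_equal(c(s$mean, s$sd, s$sd_fraction, s$n_voxels), c(1600, 0, 0, 4))
  vals2 <- array(NA_real_, c(1, 1, 3)); vals2[1, 1, ] <- 1:3
  pm2 <- parameter_map(vals2, "ms")
  m2 <- array(TRUE, c(1, 1, 3))
  s2 <- roi_summary(pm2, m2)
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2 / 3))            # population divisor
  expect_equal(roi_summary(pm2, m2, sd_divisor = "n-1")$sd, 1)
  expect_error(roi_summary(pm2, array(FALSE, c(1, 1, 3))), "no finite")
  # merging disjoint masks gives the count-weighted mean
  vals3 <- array(c(10, 10, 40), c(1, 1, 3))
  pm3 <- parameter_map(vals3, "ms")
  ma <- array(c(TRUE, TRUE, FALSE), c(1, 1, 3))
  mb <- array(c(FALSE, FALSE, TRUE), c(1, 1, 3))
  expect_equal(roi_summary(pm3, ma | mb)$mean,
               (2 * roi_summary(pm3, ma)$mean + roi_summary(pm3, mb)$mean) / 3)
})

test_that("noiseless phantom ROI means equal ground truth; WK spread exceeds cortical", {
  mol <- simulate_molli_series(test_lm, test_pars, noise_sd = 0)
  t1map <- fit_t1_map(mol)
  rois <- define_standard_rois(test_lm, seed = 3)
  cx <- roi_summary(t1map, rasterize_roi(rois, test_lm, "Cx"))
  expect_equal(cx$mean, test_pars$cortex$t1_ms, tolerance = 1e-9)
  rep <- roi_summary(t1map, rasterize_roi(rois, test_lm, "repCx"))
  expect_equal(rep$mean, cx$mean, tolerance = 1e-9)   # homogeneous compartment
  wk <- roi_summary(t1map, rasterize_roi(rois, test_lm, "WK"))
  expect_gt(wk$sd_fraction, cx$sd_fraction)
  expect_gt(wk$sd_fraction, rep$sd_fraction)
})

test_that("representative-cortex sampling error shrinks as the ROI grows", {
  # noisy map built directly: homogeneous cortex + voxel noise
  vals <- array(NA_real_, dim(test_lm$labels))
  set.seed(99)
  vals[test_lm$labels == 1L] <- 1600
  sl <- which.max(apply(test_lm$labels == 1L, 1, sum))
  gaps <- numeric(0)
  for (r_mm in c(2, 4)) {
    diffs <- vapply(1:100, function(s) {
      rois <- define_standard_rois(test_lm, slice_index = sl, kinds = "repCx",
                                   seed = s, rep_cx_radius_mm = r_mm)
      noisy <- vals
      noisy[test_lm$labels == 1L] <- 1600 + rnorm(sum(test_lm$labels == 1L), 0, 50)
      pmap <- parameter_map(noisy, "ms")
      m <- rasterize_roi(rois, test_lm, "repCx")
      abs(mean(noisy[m]) - 1600)
    }, 1)
    gaps <- c(gaps, mean(diffs))
  }
  expect_lt(gaps[2], gaps[1])
})

test_that("cortex:medulla ratios reproduce the published worked examples", {
  expect_equal(round(cortex_medulla_ratio(1630.2, 1975.8), 2), 0.83)
  expect_equal(round(cortex_medulla_ratio(221.0, 95.8), 1), 2.3)
  expect_equal(cortex_medulla_ratio(1500, 1500), 1)
  expect_error(cortex_medulla_ratio(100, 0), "zero")
  tab <- cortex_medulla_ratio_table()
  t1_all <- tab$ratio[tab$sequence == "T1" & tab$group == "All"]
  expect_equal(round(t1_all, 2), 0.83)
  pc_tx <- tab$ratio[tab$sequence == "pCASL" & tab$group == "Tx"]
  expect_equal(round(pc_tx, 1), 3.3)
})

test_that("within-ROI spread report matches the published arithmetic", {
  # cohort-level worked examples: mean ROI SD over cohort mean value
  ref <- sd_fraction_reference()
  expect_equal(ref$sd_fraction_pct[ref$sequence == "T1" & ref$roi_kind == "WK"], 20.0)
  expect_equal(ref$sd_fraction_pct[ref$sequence == "pCASL" & ref$roi_kind == "WK"], 55.4)
  # subject-level report: constant maps give zero spread
  d <- data.frame(subject = c("a", "b"), roi_kind = "WK", sequence = "T1",
                  mean = c(1500, 1700), sd = c(0, 0), units = "ms")
  rep <- sd_fraction_report(d)
  expect_equal(rep$sd_fraction_pct, 0)
  expect_equal(rep$mean_roi_sd, 0)
  d$units <- c("ms", "s")
  expect_error(sd_fraction_report(d), "unit mismatch")
})
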