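# Threshold segmentation, background region, calibration factor, AThA, TU.

test_that("threshold segmentation matches hand-checked row examples", {
  row <- matrix(c(100, 400, 1000, 500, 50), nrow = 1)
  r40 <- segment_threshold(row, 0.4)
  expect_equal(r40$p_max, 1000)
  expect_equal(sort(row[r40$mask]), c(400, 500, 1000))
  expect_equal(r40$n_roi, 1900)
  r25 <- segment_threshold(row, 0.25)
  expect_equal(r25$n_roi, 1900)
  expect_error(segment_threshold(matrix(0, 3, 3), 0.4), "no positive")
  expect_error(segment_threshold(row, 1.2), "fraction")
})

test_that("segmentation keeps only the component containing the maximum", {
  img <- matrix(0, 12, 12)
  img[2:4, 2:4] <- 50          # bright blob A
  img[9:11, 9:11] <- 60        # brighter blob B, separated
  r <- segment_threshold(img, 0.4)
  expect_true(all(which(r$mask) %in% which(img == 60)))
  expect_equal(r$n_roi, 9 * 60)
})

test_that("segmentation equals brute-force flood fill on random 3-D grids", {
  set.seed(42)
  for (rep in 1:5) {
    arr <- array(stats::rpois(20^3, 2), c(20, 20, 20))
    arr[sample(length(arr), 40)] <- 50 + stats::rpois(40, 30)
    r <- segment_threshold(arr, 0.4)
    oracle <- flood_fill_component(arr >= 0.4 * max(arr), which.max(arr))
    expect_identical(r$mask, oracle)
    expect_equal(r$n_roi, sum(arr[oracle]))
  }
})

test_that("background region sums a caudal rectangle scaled to ROI area", {
  img <- matrix(0, 20, 20)
  img[8:11, 5:8] <- 100                   # 16-pixel thyroid blob
  roi <- segment_threshold(raw_planar(img + 3), 0.9)  # uniform background 3
  bg <- background_region(raw_planar(img + 3), roi)
  expect_equal(bg$n_back, sum(roi$mask) * 3)
  # zero background
  expect_equal(background_region(raw_planar(img), roi)$n_back, 0)
  # gradient field: equals direct summation over the placed rectangle
  grad <- matrix(rep(seq_len(20), each = 20), 20, 20) + img
  bg2 <- background_region(raw_planar(grad), roi)
  expect_equal(bg2$n_back_raw, sum(grad[bg2$mask]))
  expect_equal(bg2$n_back, bg2$n_back_raw * sum(roi$mask) / bg2$area_px)
  # placement error when no caudal space remains
  img_low <- matrix(0, 20, 20); img_low[8:11, 16:19] <- 100
  roi_low <- segment_threshold(raw_planar(img_low + 1), 0.9)
  expect_error(background_region(raw_planar(img_low + 1), roi_low),
               "insufficient space")
})

test_that("calibration factor is the counts-per-activity-time ratio", {
  f <- calibration_factor(59580, 1.0, 900, "Planar")
  expect_equal(f$value, 66.2, tolerance = 1e-12)
  expect_true(f$valid)
  f0 <- calibration_factor(0, 1, 900, "Planar")
  expect_equal(f0$value, 0)
  expect_false(f0$valid)
  f2 <- calibration_factor(2 * 59580, 2.0, 900, "Planar")
  expect_equal(f2$value, f$value)
  expect_error(calibration_factor(10, 0, 900), "positive")
})

test_that("modality calibration over a ladder reports mean, SD and linearity", {
  a0 <- c(1, 2, 5, 10)
  a_acq <- decay_averaged_activity(a0, 900)
  n <- 66 * a_acq * 900                      # exactly proportional counts
  cal <- calibrate_modality(a0, n, 900, "Planar")
  expect_equal(cal$fcal$value, 66, tolerance = 1e-12)
  expect_equal(cal$fcal$sd, 0, tolerance = 1e-12)
  expect_gt(cal$r, 0.9999)
  expect_error(calibrate_modality(1, 66, 900), "at least 2")
})

test_that("AThA inverts the calibration relation", {
  f <- calibration_factor(59580, 1, 900, "Tomo-AC")
  expect_equal(estimate_atha(f$value * 900 * 5, f, 900), 5)
  expect_equal(estimate_atha(0, f, 900), 0)
  expect_error(estimate_atha(10, f, -1), "positive")
})

test_that("net injected activity subtracts the residual syringe", {
  expect_equal(net_injected_activity(82.0, 2.8), 79.2)
  expect_equal(net_injected_activity(80, 0), 80)
  expect_equal(net_injected_activity(5, 5), 0)
  expect_error(net_injected_activity(2, 5), ">=")
  # optional decay correction to injection time
  a <- net_injected_activity(82, 2.8, t_full_s = -600, t_empty_s = 600,
                             decay_correct = TRUE)
  lam <- log(2) / 21600
  expect_equal(a, 82 * exp(-lam * 600) - 2.8 * exp(lam * 600))
})

test_that("thyroid uptake inverts, clips and rejects tomographic background", {
  f <- calibration_factor(59580, 1, 900, "Planar")
  dt <- 900; a_i <- 80
  u <- thyroid_uptake(0.05 * f$value * dt * a_i, 0, f, a_i, dt, "Planar")
  expect_equal(u$tu, 5.0)
  expect_equal(thyroid_uptake(1234, 1234, f, a_i, dt, "Planar")$tu, 0)
  expect_warning(z <- thyroid_uptake(10, 20, f, a_i, dt, "Planar"), "clipped")
  expect_equal(z$tu, 0)
  expect_error(thyroid_uptake(100, 5, f, a_i, dt, "Tomo-AC"), "background")
  expect_error(thyroid_uptake(100, 0, f, 0, dt, "Planar"), "positive")
})

test_that("uptake equals AThA over injected activity and is scale invariant", {
  dt <- 1200; a_i <- 79.2
  for (n in c(1e4, 5e5)) {
    f <- calibration_factor(6e4, 1, dt, "Tomo-AC")
    expect_equal(thyroid_uptake(n, 0, f, a_i, dt, "Tomo-AC")$tu,
                 estimate_atha(n, f, dt) / a_i * 100, tolerance = 1e-12)
    # rescaling the sensitivity rescales counts and fcal, leaving TU fixed
    for (c_scale in c(0.5, 3)) {
      f2 <- calibration_factor(6e4 * c_scale, 1, dt, "Tomo-AC")
      expect_equal(thyroid_uptake(n * c_scale, 0, f2, a_i, dt, "Tomo-AC")$tu,
                   thyroid_uptake(n, 0, f, a_i, dt, "Tomo-AC")$tu,
                   tolerance = 1e-12)
    }
  }
})

test_that("uptake is monotone in thyroid counts, background and activity", {
  f <- calibration_factor(6e4, 1, 900, "Planar")
  tu <- function(n, b, a) thyroid_uptake(n, b, f, a, 900, "Planar")$tu
  expect_true(tu(2e4, 0, 80) > tu(1e4, 0, 80))
  expect_true(tu(2e4, 5e3, 80) < tu(2e4, 0, 80))
  expect_true(tu(2e4, 0, 90) < tu(2e4, 0, 80))
})
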