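# Phantom generators: geometry, activity conservation, cohort sampling.

test_that("calibration phantom conserves activity and voxelizes a 15 ml vial", {
  g2 <- grid_spec(c(72, 72, 72), 2)
  ph <- make_calibration_phantom(1.0, g2)
  expect_equal(sum(ph$activity), 1.0, tolerance = 1e-12)
  # voxelized vial volume within 10% of 15 ml at 2 mm voxels
  expect_lt(abs(ph$truth$volume_cc - 15) / 15, 0.10)
  # cold phantom: zero activity but attenuating body
  cold <- make_calibration_phantom(0, g2)
  expect_true(all(cold$activity == 0))
  expect_gt(sum(cold$mu), 0)
  # mu map holds only air and water values
  expect_setequal(unique(as.vector(ph$mu)), c(0, 0.154))
})

test_that("calibration phantom activity sits only in the vial, 20 mm deep", {
  g <- grid_spec(c(40, 40, 40), 4.92)
  ph <- make_calibration_phantom(5, g)
  expect_true(all(ph$activity[!ph$truth$source_mask] == 0))
  idx <- which(ph$truth$source_mask, arr.ind = TRUE)
  depth_mm <- mean(idx[, 2] - 0.5) * g$voxel_mm[2] -
    (g$extent_mm[2] / 2 - 127 / 2)
  expect_lt(abs(depth_mm - 20), g$voxel_mm[2])
  expect_error(make_calibration_phantom(1, grid_spec(c(10, 10, 10), 4.92)),
               "too small")
})

test_that("thyroid phantom volume converges to the request as voxels shrink", {
  for (v in c(3.2, 19)) {
    ph1 <- make_thyroid_phantom(v, 1, grid_spec(c(160, 160, 160), 1))
    expect_lt(abs(ph1$truth$voxelized_volume_cc - v) / v, 0.05)
  }
  # coarser voxels are less accurate but still converging
  ph2 <- make_thyroid_phantom(19, 1, grid_spec(c(80, 80, 80), 2))
  expect_lt(abs(ph2$truth$voxelized_volume_cc - 19) / 19, 0.12)
})

test_that("thyroid phantom is linear in activity and instantiable at 3.2 cc", {
  g <- grid_spec(c(40, 40, 40), 4.92)
  small <- make_thyroid_phantom(3.2, 0.4, g)
  expect_gt(sum(small$truth$thyroid_mask), 0)
  expect_equal(sum(small$activity), 0.4, tolerance = 1e-12)
  a <- make_thyroid_phantom(11.4, 2, g)
  b <- make_thyroid_phantom(11.4, 4, g)
  expect_equal(b$activity, 2 * a$activity, tolerance = 1e-12)
  # mu map holds only the configured air/water/bone values
  expect_setequal(unique(as.vector(a$mu)), c(0, 0.154, 0.25))
  expect_error(make_thyroid_phantom(500, 1, g), "capacity")
})

test_that("cohort sampling is seeded, in range, and centered near 80 MBq", {
  p1 <- sample_cohort_params(23, seed = 7)
  p2 <- sample_cohort_params(23, seed = 7)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 23)
  expect_true(all(p1$tu_true_pct > 1 & p1$tu_true_pct < 12))
  # law of large numbers on the injected-activity model
  big <- sample_cohort_params(1e4, seed = 11)
  expect_lt(abs(mean(big$a_i_mbq) - 80), 3 * 3.7 / sqrt(1e4))
  expect_error(sample_cohort_params(3, 1, tu_range = c(0, 120)), "tu_range")
})

test_that("patient cases carry truth uptake and conserve total activity", {
  g <- grid_spec(c(32, 32, 32), 4.92)
  co <- make_patient_cohort(3, seed = 5, g)
  for (k in 1:3) {
    vol <- co$cases[[k]]
    p <- co$params[k, ]
    expect_equal(sum(vol$activity[vol$truth$thyroid_mask]),
                 p$tu_true_pct * p$a_i_mbq / 100, tolerance = 1e-9)
    expect_equal(vol$truth$tu_pct, p$tu_true_pct)
    expect_true(all(vol$activity >= 0))
  }
  co2 <- make_patient_cohort(3, seed = 5, g)
  expect_equal(co$cases[[2]]$activity, co2$cases[[2]]$activity)
})
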