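# Acquisition simulator: decay averaging, attenuated projection physics,
# planar/SPECT expectation and noise properties.

test_that("decay-averaged activity matches quadrature and closed forms", {
  # near-zero duration: A_acq -> A0
  expect_equal(decay_averaged_activity(10, 1e-6, 21600), 10, tolerance = 1e-9)
  # clinical-protocol planar acquisition vs numerical quadrature
  expect_equal(decay_averaged_activity(10, 900, 21600),
               decay_quadrature(10, 900, 21600), tolerance = 1e-8)
  # one half-life: a0 * (1/2) / ln 2
  expect_equal(decay_averaged_activity(10, 21600, 21600),
               10 * 0.5 / log(2), tolerance = 1e-12)
  # quadrature agreement across a parameter sweep
  for (dt in c(60, 600, 1200, 43200))
    expect_equal(decay_averaged_activity(7, dt, 21650),
                 decay_quadrature(7, dt, 21650), tolerance = 1e-8)
  expect_error(decay_averaged_activity(1, -5, 21600), "positive")
  expect_error(decay_averaged_activity(1, 900, 0), "positive")
})

test_that("attenuated projection obeys Beer-Lambert through 2 cm of water", {
  n <- 16
  act <- array(0, c(n, n, n)); act[8, 12, 8] <- 1   # point source, mu-free voxel
  mu0 <- array(0, c(n, n, n))
  mu <- mu0; mu[8, 7:10, 8] <- 0.154                # 4 x 5 mm = 2 cm water slab
  par <- acq_params("planar", duration_s = 1, psf_fwhm_mm = 0,
                    scatter_fraction = 0, half_life_s = 1e12)
  p_free <- attenuated_projection(raw_volume(act, mu0, 5), 0, par)
  p_att <- attenuated_projection(raw_volume(act, mu, 5), 0, par)
  expect_equal(sum(p_att) / sum(p_free), exp(-0.154 * 2), tolerance = 1e-9)
})

test_that("projection expectation is linear in activity and sensitivity", {
  g <- grid_spec(c(32, 32, 32), 4.92)
  ph <- make_calibration_phantom(2, g)
  par <- acq_params("planar")
  p1 <- attenuated_projection(ph, 0, par)
  ph2 <- ph; ph2$activity <- 3 * ph$activity
  expect_equal(attenuated_projection(ph2, 0, par), 3 * p1, tolerance = 1e-12)
  par2 <- acq_params("planar", sensitivity_cps_mbq = 2 * par$sensitivity_cps_mbq)
  expect_equal(attenuated_projection(ph, 0, par2), 2 * p1, tolerance = 1e-12)
  zero <- ph; zero$activity[] <- 0
  expect_true(all(attenuated_projection(zero, 123.4, par) == 0))
})

test_that("unattenuated total planar counts equal sensitivity x time x A_acq", {
  n <- 24
  act <- array(0, c(n, n, n)); act[9:14, 9:14, 9:14] <- 1 / 216
  vol <- raw_volume(act, array(0, c(n, n, n)), 4)
  par <- acq_params("planar", duration_s = 900, psf_fwhm_mm = 0,
                    scatter_fraction = 0)
  img <- simulate_planar(vol, par)
  expect_equal(sum(img$main$counts),
               par$sensitivity_cps_mbq * 900 * decay_averaged_activity(1, 900),
               tolerance = 1e-6)
  expect_true(all(img$scatter$counts == 0))
})

test_that("Poisson sampling has unit index of dispersion", {
  g <- grid_spec(c(32, 32, 32), 4.92)
  ph <- make_calibration_phantom(0.5, g)
  expectation <- simulate_planar(ph, acq_params("planar"))$main$counts
  keep <- expectation > 20
  expect_gt(sum(expectation[keep]), 1e4)
  chi2 <- 0; nterm <- 0
  for (s in 1:40) {
    x <- simulate_planar(ph, acq_params("planar", seed = s))$main$counts
    chi2 <- chi2 + sum((x[keep] - expectation[keep])^2 / expectation[keep])
    nterm <- nterm + sum(keep)
  }
  expect_gt(chi2 / nterm, 0.8)
  expect_lt(chi2 / nterm, 1.2)
})

test_that("scatter fraction zero yields an empty scatter window", {
  g <- grid_spec(c(32, 32, 32), 4.92)
  ph <- make_calibration_phantom(1, g)
  out <- simulate_planar(ph, acq_params("planar", scatter_fraction = 0))
  expect_true(all(out$scatter$counts == 0))
})

test_that("SPECT projections honour symmetry, linearity and per-step decay", {
  n <- 24
  act <- array(0, c(n, n, n))
  ctr <- c(12, 12, 12); act[ctr[1] + (-1:0), ctr[2] + (-1:0), ctr[3] + (-1:0)] <- 1 / 8
  mu <- array(0, c(n, n, n))
  vol <- raw_volume(act, mu, 5)
  par <- acq_params("spect", n_projections = 12, n_heads = 2,
                    psf_fwhm_mm = 0, scatter_fraction = 0, half_life_s = 1e12)
  sg <- simulate_spect(vol, par)
  tot <- apply(sg$main$counts, 3, sum)
  # centered symmetric source: opposing angles agree in expectation
  expect_equal(tot[1:6], tot[7:12], tolerance = 1e-6)
  # linearity in A0
  vol2 <- vol; vol2$activity <- 2 * vol2$activity
  expect_equal(apply(simulate_spect(vol2, par)$main$counts, 3, sum), 2 * tot,
               tolerance = 1e-9)
  # with decay dominating interpolation jitter, expected totals decrease
  # monotonically over each head's angular steps
  par_decay <- acq_params("spect", n_projections = 12, n_heads = 2,
                          psf_fwhm_mm = 0, scatter_fraction = 0,
                          half_life_s = 600)
  td <- apply(simulate_spect(vol, par_decay)$main$counts, 3, sum)
  expect_true(all(diff(td[1:6]) < 0))
  expect_true(all(diff(td[7:12]) < 0))
})
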