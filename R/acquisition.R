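# Planar and SPECT acquisition simulator: radioactive decay during the
# acquisition, attenuated parallel-beam projection, detector PSF, additive
# scatter split between energy windows, and Poisson counting noise.
#
# The simulator works at the physics level; detector microphysics and vendor
# post-processing are not modeled. The effective sensitivity and PSF FWHM
# are the camera model: they are chosen once so the simulated planar
# cross-calibration factor lands near the 60-70 counts/(MBq s) scale typical
# of a large-field CZT camera at 140 keV.

#' Acquisition parameter set
#'
#' @param mode `"planar"` or `"spect"`.
#' @param duration_s Planar: total acquisition time (default 900 s). SPECT:
#'   per-projection time (default 20 s).
#' @param n_projections Number of SPECT projections over 360 degrees
#'   (default 60); ignored for planar.
#' @param n_heads Number of detector heads acquiring simultaneously
#'   (default 2): opposed heads each cover `n_projections / n_heads`
#'   angular steps, so the wall-clock acquisition lasts
#'   `n_projections / n_heads * duration_s` seconds.
#' @param psf_fwhm_mm Effective detector PSF FWHM in mm (default 3.5, the calibrated effective end-to-end resolution including resolution recovery).
#' @param scatter_fraction Scatter-to-primary fraction added to the main
#'   energy window (default 0.2); must be in [0, 1).
#' @param sensitivity_cps_mbq Effective system sensitivity, counts per
#'   (MBq s) for an unattenuated source (default 83, calibrated so the simulated planar cross-calibration factor lands near 66 counts/(MBq s)).
#' @param half_life_s Radionuclide half-life in seconds (default 21600,
#'   the 6 h nominal Tc-99m value).
#' @param seed Integer seed for Poisson sampling, or `NULL` for the
#'   noiseless expectation image.
#' @param scatter_blur_fwhm_mm FWHM of the broad Gaussian that shapes the
#'   scatter component (default 30 mm).
#' @param scatter_window_share Fraction of the scatter component recorded in
#'   the lower (scatter) energy window; defaults to `1/dew_k_default()` so
#'   dual-energy-window subtraction is unbiased in expectation.
#' @param windows Energy-window descriptor (documentation only): main window
#'   140 keV +/- 10% planar or +/- 7.5% SPECT, scatter window 120 keV +/- 5%.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(mode = c("planar", "spect"),
                       duration_s = NULL,
                       n_projections = 60,
                       n_heads = 2,
                       psf_fwhm_mm = 3.5,
                       scatter_fraction = 0.2,
                       sensitivity_cps_mbq = 83,
                       half_life_s = TC99M_HALF_LIFE_S,
                       seed = NULL,
                       scatter_blur_fwhm_mm = 30,
                       scatter_window_share = 1 / dew_k_default(),
                       windows = NULL) {
  mode <- match.arg(mode)
  if (is.null(duration_s)) duration_s <- if (mode == "planar") 900 else 20
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("`scatter_fraction` must be in [0, 1)")
  if (sensitivity_cps_mbq <= 0) stop("`sensitivity_cps_mbq` must be positive")
  if (n_projections < 1) stop("`n_projections` must be >= 1")
  if (n_heads < 1 || n_projections %% n_heads != 0)
    stop("`n_heads` must divide `n_projections`")
  if (half_life_s <= 0) stop("`half_life_s` must be positive")
  if (is.null(windows))
    windows <- if (mode == "planar")
      list(main = "140 keV +/- 10%", scatter = "120 keV +/- 5%")
    else
      list(main = "140 keV +/- 7.5%", scatter = "120 keV +/- 5%")
  structure(list(
    mode = mode, duration_s = duration_s,
    n_projections = as.integer(n_projections), n_heads = as.integer(n_heads),
    psf_fwhm_mm = psf_fwhm_mm, scatter_fraction = scatter_fraction,
    sensitivity_cps_mbq = sensitivity_cps_mbq, half_life_s = half_life_s,
    seed = seed, scatter_blur_fwhm_mm = scatter_blur_fwhm_mm,
    scatter_window_share = scatter_window_share, windows = windows
  ), class = "acq_params")
}

# Default dual-energy-window scale factor: 1.1 scaled by the ratio of the
# SPECT main window width (140 keV +/- 7.5% -> 21 keV) to the scatter window
# width (120 keV +/- 5% -> 12 keV).
dew_k_default <- function() 1.1 * (0.15 * 140) / (0.10 * 120)

#' Decay-averaged activity over an acquisition
#'
#' Mean activity of an exponentially decaying source over `[0, dt]`:
#' `A_acq = a0 * (1 - exp(-lambda dt)) / (lambda dt)` with
#' `lambda = ln 2 / half_life` — the closed form of the time integral of
#' `a0 * exp(-lambda t)` divided by `dt`.
#'
#' @param a0 Activity at acquisition start, MBq (>= 0).
#' @param dt Acquisition duration, s (> 0).
#' @param half_life Half-life, s (> 0).
#' @return Decay-averaged activity in MBq.
#' @examples
#' decay_averaged_activity(10, 900, 21600)  # ~9.857 MBq over 15 min
#' @export
decay_averaged_activity <- function(a0, dt, half_life = TC99M_HALF_LIFE_S) {
  if (any(a0 < 0)) stop("`a0` must be non-negative")
  if (any(dt <= 0)) stop("`dt` must be positive")
  if (any(half_life <= 0)) stop("`half_life` must be positive")
  lam <- log(2) / half_life
  # -expm1 avoids cancellation of 1 - exp(-x) for very short acquisitions
  a0 * (-expm1(-lam * dt)) / (lam * dt)
}

# Cumulative transmission exp(-integral mu dl) from every voxel to a
# detector on the anterior (low-y) side, for a volume already rotated into
# detector frame. Includes half the emitting voxel's own attenuation.
transmission_to_detector <- function(mu_rot, dy_cm) {
  d <- dim(mu_rot)
  tr <- array(0, d)
  run <- matrix(0, d[1], d[3])
  for (j in seq_len(d[2])) {
    sl <- mu_rot[, j, ]
    tr[, j, ] <- exp(-dy_cm * (run + 0.5 * sl))
    run <- run + sl
  }
  tr
}

#' Attenuated parallel-beam projection
#'
#' Expected planar count image of an activity volume seen from gantry angle
#' `angle_deg` (0 = anterior view): the volume is rotated into detector
#' frame, each voxel's emission is weighted by `exp(-integral of mu)` along
#' its ray to the detector, rays are summed, and the result is convolved
#' with the Gaussian detector PSF and scaled by
#' `sensitivity * duration * decay-average factor`. Linear in activity and
#' in sensitivity.
#'
#' @param vol An `activity_volume`.
#' @param angle_deg Gantry angle in degrees; values outside [0, 360) are
#'   normalized.
#' @param params An [acq_params()].
#' @param decay_factor Multiplicative decay weighting (default the
#'   decay-average factor over `params$duration_s`).
#' @param transmission Optional precomputed transmission array for this
#'   angle (as from the internal cache); mainly for the reconstruction code.
#' @return Matrix of expected counts, dimensions `[x, z]` of the volume
#'   grid, pixel size equal to the voxel size.
#' @export
attenuated_projection <- function(vol, angle_deg, params,
                                  decay_factor = NULL, transmission = NULL) {
  grid <- vol$grid
  angle_deg <- angle_deg %% 360
  if (is.null(decay_factor))
    decay_factor <- decay_averaged_activity(1, params$duration_s, params$half_life_s)
  act_r <- rotate_volume_xy(vol$activity, -angle_deg)
  if (is.null(transmission)) {
    mu_r <- rotate_volume_xy(vol$mu, -angle_deg)
    transmission <- transmission_to_detector(mu_r, grid$voxel_mm[2] / 10)
  }
  w <- act_r * transmission
  p <- colSums(aperm(w, c(2, 1, 3)))           # sum over y -> [x, z]
  p <- blur_matrix(p, params$psf_fwhm_mm, grid$voxel_mm[c(1, 3)])
  p * params$sensitivity_cps_mbq * params$duration_s * decay_factor
}

new_planar_image <- function(counts, pixel_mm, duration_s, window) {
  structure(list(counts = counts, pixel_mm = pixel_mm,
                 duration_s = duration_s, window = window),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %d x %d px @ %.3g mm, %g s, %s window, %.4g counts\n",
              nrow(x$counts), ncol(x$counts), x$pixel_mm[1], x$duration_s,
              x$window, sum(x$counts)))
  invisible(x)
}

# Split a primary expectation image into (main window, scatter window):
# scatter = scatter_fraction x broad blur of primary; the main window keeps
# primary + (1 - share) complement handled via share bookkeeping.
scatter_split_2d <- function(primary, params, pixel_mm) {
  if (params$scatter_fraction == 0)
    return(list(main = primary, scatter = primary * 0))
  s <- blur_matrix(primary, params$scatter_blur_fwhm_mm, pixel_mm) *
    params$scatter_fraction
  list(main = primary + s, scatter = s * params$scatter_window_share)
}

poisson_or_expectation <- function(x, sample) {
  if (!sample) return(x)
  array(stats::rpois(length(x), pmax(x, 0)), dim = dim(x))
}

#' Simulate a planar acquisition
#'
#' Anterior-view (0 degree) attenuated projection of the volume over the
#' full planar duration, with additive scatter split between the main and
#' scatter energy windows. With a seed the images are Poisson realizations;
#' with `seed = NULL` they are noiseless expectations.
#'
#' @param vol An `activity_volume`.
#' @param params An [acq_params()] with `mode = "planar"`.
#' @return List with `main` and `scatter` [planar_image]s.
#' @export
simulate_planar <- function(vol, params = acq_params("planar")) {
  if (params$mode != "planar") stop("`params$mode` must be 'planar'")
  primary <- attenuated_projection(vol, 0, params)
  sw <- scatter_split_2d(primary, params, vol$grid$voxel_mm[c(1, 3)])
  sample <- !is.null(params$seed)
  if (sample) set.seed(as.integer(params$seed))
  list(
    main = new_planar_image(poisson_or_expectation(sw$main, sample),
                            vol$grid$voxel_mm[c(1, 3)], params$duration_s, "main"),
    scatter = new_planar_image(poisson_or_expectation(sw$scatter, sample),
                               vol$grid$voxel_mm[c(1, 3)], params$duration_s, "scatter")
  )
}

new_sinogram <- function(counts, angles_deg, proj_duration_s, grid, window) {
  stopifnot(all(diff(angles_deg) > 0), all(angles_deg >= 0), all(angles_deg < 360))
  structure(list(counts = counts, angles_deg = angles_deg,
                 proj_duration_s = proj_duration_s, grid = grid,
                 window = window),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d projections x %d x %d px, %g s each, %s window\n",
              length(x$angles_deg), dim(x$counts)[1], dim(x$counts)[2],
              x$proj_duration_s, x$window))
  invisible(x)
}

#' Simulate a SPECT acquisition
#'
#' `n_projections` equally spaced projections over 360 degrees, each of
#' `duration_s` seconds, with the same per-angle physics as the planar
#' simulator. The opposed detector heads acquire simultaneously: angular
#' step `s` (of `n_projections / n_heads` steps) records `n_heads`
#' projections 360/n_heads degrees apart, all with the decay factor of the
#' elapsed wall time at that step, so expected totals decrease
#' monotonically over the steps of each head.
#'
#' @param vol An `activity_volume`.
#' @param params An [acq_params()] with `mode = "spect"`.
#' @return List with `main` and `scatter` [sinogram]s; counts arrays are
#'   `[x, z, angle]`.
#' @export
simulate_spect <- function(vol, params = acq_params("spect")) {
  if (params$mode != "spect") stop("`params$mode` must be 'spect'")
  grid <- vol$grid
  nproj <- params$n_projections
  angles <- (seq_len(nproj) - 1) * 360 / nproj
  lam <- log(2) / params$half_life_s
  f1 <- decay_averaged_activity(1, params$duration_s, params$half_life_s)
  steps <- nproj %/% params$n_heads
  d <- c(grid$shape[1], grid$shape[3], nproj)
  main <- array(0, d); scat <- array(0, d)
  px <- grid$voxel_mm[c(1, 3)]
  for (j in seq_len(nproj)) {
    f <- exp(-lam * ((j - 1) %% steps) * params$duration_s) * f1
    primary <- attenuated_projection(vol, angles[j], params, decay_factor = f)
    sw <- scatter_split_2d(primary, params, px)
    main[, , j] <- sw$main
    scat[, , j] <- sw$scatter
  }
  sample <- !is.null(params$seed)
  if (sample) {
    set.seed(as.integer(params$seed))
    main <- poisson_or_expectation(main, TRUE)
    scat <- poisson_or_expectation(scat, TRUE)
  }
  list(
    main = new_sinogram(main, angles, params$duration_s, grid, "main"),
    scatter = new_sinogram(scat, angles, params$duration_s, grid, "scatter")
  )
}
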