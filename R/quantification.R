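# Quantification chain: percent-of-maximum threshold segmentation with
# connected components, camera cross-calibration factor, absolute thyroid
# activity (AThA) and thyroid uptake (TU).

# Shift a logical array by an integer offset, padding with FALSE.
shift_logical <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o) + o; src[[k]] <- seq_len(d[k] - o) }
    else        { dst[[k]] <- seq_len(d[k] + o);     src[[k]] <- seq_len(d[k] + o) - o }
    if (length(dst[[k]]) == 0) return(out)
  }
  if (length(d) == 2L) {
    out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  }
  out
}

# All nonzero king-move offsets for `ndim` dimensions (8 in 2-D, 26 in 3-D).
neighbor_offsets <- function(ndim) {
  g <- do.call(expand.grid, rep(list(-1:1), ndim))
  g <- as.matrix(g[rowSums(abs(g)) > 0, , drop = FALSE])
  unname(g)
}

# Connected component of `mask` containing `seed_index` (flat index), with
# 8-connectivity in 2-D / 26-connectivity in 3-D, by iterative dilation.
connected_component <- function(mask, seed_index) {
  d <- dim(mask)
  offs <- neighbor_offsets(length(d))
  comp <- array(FALSE, d)
  comp[seed_index] <- TRUE
  repeat {
    nb <- comp
    for (r in seq_len(nrow(offs))) nb <- nb | shift_logical(comp, offs[r, ])
    grown <- nb & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

image_counts <- function(image) {
  if (inherits(image, "planar_image")) image$counts
  else if (inherits(image, "spect_volume")) image$counts
  else if (is.array(image) || is.matrix(image)) image
  else stop("`image` must be a planar_image, spect_volume, matrix or array")
}

#' Percent-of-maximum threshold segmentation
#'
#' Finds the global count maximum `Pmax`, keeps all pixels/voxels whose
#' value is at least `fraction * Pmax` (inclusive threshold), and returns
#' the connected component containing the maximum (8-connectivity in 2-D,
#' 26-connectivity in 3-D). The standard thresholds are 25% of Pmax for
#' planar ROIs and 40% of Pmax for SPECT VOIs.
#'
#' @param image A `planar_image`, `spect_volume`, matrix or array with at
#'   least one positive value.
#' @param fraction Threshold fraction in (0, 1).
#' @return An object of class `region` with elements `mask` (logical array),
#'   `indices`, `p_max`, `threshold_fraction` and `n_roi` (summed counts of
#'   the members).
#' @examples
#' m <- matrix(c(100, 400, 1000, 500, 50), nrow = 1)
#' segment_threshold(m, 0.4)$n_roi  # 1900
#' @export
segment_threshold <- function(image, fraction) {
  counts <- image_counts(image)
  if (is.matrix(counts)) dim(counts) <- dim(counts)   # keep 2-D
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  p_max <- max(counts)
  if (!is.finite(p_max) || p_max <= 0)
    stop("segmentation failed: image has no positive counts")
  mask <- counts >= fraction * p_max
  comp <- connected_component(mask, which.max(counts))
  structure(list(
    mask = comp,
    indices = which(comp, arr.ind = TRUE),
    p_max = p_max,
    threshold_fraction = fraction,
    n_roi = sum(counts[comp])
  ), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %d members, Pmax = %.4g, threshold %.0f%%, N_ROI = %.6g\n",
              sum(x$mask), x$p_max, 100 * x$threshold_fraction, x$n_roi))
  invisible(x)
}

#' Background region below a planar thyroid ROI
#'
#' Places a rectangular background ROI directly caudal to the thyroid ROI
#' (toward larger z / image bottom), separated by a configurable gap, with
#' the same x-extent as the thyroid ROI's bounding box and enough rows to
#' cover at least as many pixels as the thyroid ROI. `n_back` is the summed
#' background counts rescaled to the thyroid ROI's pixel count, the
#' convention used for background-corrected planar uptake.
#'
#' @param img A `planar_image` (axes `[x, z]`, z increasing caudally).
#' @param thyroid A `region` from [segment_threshold()] on `img`.
#' @param gap_px Gap between thyroid ROI and background rectangle in pixels.
#' @return A list with `mask`, `n_back` (area-scaled), `n_back_raw` and
#'   `area_px`.
#' @export
background_region <- function(img, thyroid, gap_px = 1) {
  counts <- image_counts(img)
  if (length(dim(counts)) != 2L) stop("background regions are planar-only")
  idx <- which(thyroid$mask, arr.ind = TRUE)
  x_rng <- range(idx[, 1])
  z_max <- max(idx[, 2])
  m <- nrow(idx)
  w <- x_rng[2] - x_rng[1] + 1L
  rows <- ceiling(m / w)
  z0 <- z_max + gap_px + 1L
  z1 <- z0 + rows - 1L
  if (z1 > ncol(counts))
    stop("insufficient space below the thyroid ROI for a background region")
  mask <- array(FALSE, dim(counts))
  mask[x_rng[1]:x_rng[2], z0:z1] <- TRUE
  raw <- sum(counts[mask])
  area <- sum(mask)
  list(mask = mask, n_back = raw * m / area, n_back_raw = raw, area_px = area)
}

#' Camera cross-calibration factor
#'
#' `F_cal = N_ROI / (A_acq * dt)` in counts/(MBq s), where `N_ROI` is the
#' segmented phantom-vial counts, `A_acq` the decay-averaged vial activity
#' over the acquisition and `dt` the acquisition duration.
#'
#' @param n_roi Segmented counts (>= 0).
#' @param a_acq Decay-averaged activity, MBq (> 0).
#' @param dt Acquisition duration, s (> 0).
#' @param modality One of `"Planar"`, `"Tomo-AC"`, `"Tomo-NoAC"`.
#' @param sd Optional standard deviation over repeated calibrations.
#' @return An object of class `calibration_factor` with `value`, `modality`,
#'   `sd` and `valid` (`FALSE` when `n_roi` is 0).
#' @export
calibration_factor <- function(n_roi, a_acq, dt,
                               modality = c("Planar", "Tomo-AC", "Tomo-NoAC"),
                               sd = NA_real_) {
  modality <- match.arg(modality)
  if (a_acq <= 0) stop("`a_acq` must be positive")
  if (dt <= 0) stop("`dt` must be positive")
  if (n_roi < 0) stop("`n_roi` must be non-negative")
  structure(list(value = n_roi / (a_acq * dt), modality = modality,
                 sd = sd, valid = n_roi > 0),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %s: %.4g +/- %.2g counts/(MBq s)%s\n",
              x$modality, x$value, x$sd, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' Calibrate one modality over an activity ladder
#'
#' Computes the per-level cross-calibration factor for phantom acquisitions
#' at several known activities, and summarizes the ladder: mean and SD of
#' `F_cal` and the Pearson correlation of accumulated counts versus
#' activity (the linearity check).
#'
#' @param a0 Vector of vial activities at acquisition start, MBq (>= 2
#'   levels).
#' @param n_roi Vector of segmented counts, one per level.
#' @param dt Acquisition duration used to normalize counts, s (total
#'   detector time).
#' @param modality Modality label.
#' @param half_life Half-life in s for the decay averaging.
#' @param wall_s Wall-clock duration over which the source decays; equals
#'   `dt` for planar, and `dt / n_heads` for a multi-head SPECT orbit.
#' @return A list with `fcal` (a `calibration_factor` holding the mean and
#'   SD), `r` (counts-activity Pearson r), `p_value` and `per_level`
#'   data.frame.
#' @export
calibrate_modality <- function(a0, n_roi, dt,
                               modality = c("Planar", "Tomo-AC", "Tomo-NoAC"),
                               half_life = TC99M_HALF_LIFE_S, wall_s = dt) {
  modality <- match.arg(modality)
  if (length(a0) < 2L || length(n_roi) != length(a0))
    stop("need at least 2 activity levels with matching counts")
  a_acq <- decay_averaged_activity(a0, wall_s, half_life)
  f <- n_roi / (a_acq * dt)
  if (length(a0) >= 3L) {
    ct <- stats::cor.test(n_roi, a0)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- stats::cor(n_roi, a0); p <- NA_real_   # p-value needs n > 2
  }
  fcal <- calibration_factor(mean(n_roi), mean(a_acq), dt, modality,
                             sd = stats::sd(f))
  fcal$value <- mean(f)
  list(fcal = fcal, r = r, p_value = p,
       per_level = data.frame(a0 = a0, a_acq = a_acq, n_roi = n_roi, fcal = f))
}

#' Absolute thyroid activity
#'
#' `AThA (MBq) = N_ROI,th / (F_cal * dt)`: the inversion of the calibration
#' relation applied to the segmented thyroid counts.
#'
#' @param n_roi_th Segmented thyroid counts.
#' @param fcal A `calibration_factor` or its numeric value.
#' @param dt Acquisition duration, s (> 0).
#' @return Estimated activity in MBq.
#' @export
estimate_atha <- function(n_roi_th, fcal, dt) {
  f <- if (inherits(fcal, "calibration_factor")) fcal$value else fcal
  if (f <= 0) stop("`fcal` must be positive")
  if (dt <= 0) stop("`dt` must be positive")
  n_roi_th / (f * dt)
}

#' Net injected activity
#'
#' Injected activity as the difference between the full- and empty-syringe
#' assays, optionally decay-correcting both assays to the injection time.
#'
#' @param full_syringe,empty_syringe Assayed activities, MBq.
#' @param t_full_s,t_empty_s Assay times relative to injection, s (negative
#'   = before injection); used only when `decay_correct = TRUE`.
#' @param decay_correct Apply decay correction of both assays to injection
#'   time.
#' @param half_life Half-life, s.
#' @return Net injected activity `A_i` in MBq.
#' @examples
#' net_injected_activity(82.0, 2.8)  # 79.2 MBq
#' @export
net_injected_activity <- function(full_syringe, empty_syringe,
                                  t_full_s = 0, t_empty_s = 0,
                                  decay_correct = FALSE,
                                  half_life = TC99M_HALF_LIFE_S) {
  if (any(empty_syringe < 0) || any(full_syringe < empty_syringe))
    stop("need `full_syringe` >= `empty_syringe` >= 0")
  if (decay_correct) {
    lam <- log(2) / half_life
    full_syringe <- full_syringe * exp(lam * t_full_s)
    empty_syringe <- empty_syringe * exp(lam * t_empty_s)
  }
  full_syringe - empty_syringe
}

#' Thyroid uptake
#'
#' `TU (%) = (N_ROI,th - N_back) / (F_cal * dt * A_i) * 100`, i.e. the
#' background-corrected absolute thyroid activity as a percentage of the
#' injected activity. Tomographic modalities use no background correction
#' (`n_back` must be 0). Negative net counts are clipped to zero with a
#' warning so `TU` stays in [0, 100].
#'
#' @param n_roi_th Segmented thyroid counts.
#' @param n_back Area-scaled background counts (0 for tomographic
#'   modalities).
#' @param fcal A `calibration_factor` (or numeric) for the same modality.
#' @param a_i Net injected activity, MBq (> 0).
#' @param dt Acquisition duration, s (> 0).
#' @param modality Modality label.
#' @return An object of class `uptake_result` with `tu` (%), `atha` (MBq,
#'   background-corrected), `modality`, `a_i`, `n_roi` and `n_back`.
#' @export
thyroid_uptake <- function(n_roi_th, n_back, fcal, a_i, dt,
                           modality = c("Planar", "Tomo-AC", "Tomo-NoAC")) {
  modality <- match.arg(modality)
  if (a_i <= 0) stop("`a_i` must be positive")
  if (dt <= 0) stop("`dt` must be positive")
  if (modality != "Planar" && n_back != 0)
    stop("background correction is not applied for tomographic modalities")
  f <- if (inherits(fcal, "calibration_factor")) fcal$value else fcal
  if (f <= 0) stop("`fcal` must be positive")
  net <- n_roi_th - n_back
  if (net < 0) {
    warning("negative net counts clipped to 0")
    net <- 0
  }
  atha <- net / (f * dt)
  tu <- atha / a_i * 100
  if (tu > 100) {
    warning("uptake above 100% clipped")
    tu <- 100
  }
  structure(list(tu = tu, atha = atha, modality = modality, a_i = a_i,
                 n_roi = n_roi_th, n_back = n_back),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat(sprintf("<uptake_result> %s: TU = %.2f%%, AThA = %.3g MBq (A_i = %.3g MBq)\n",
              x$modality, x$tu, x$atha, x$a_i))
  invisible(x)
}
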