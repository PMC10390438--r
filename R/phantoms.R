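# Synthetic phantom generators: ground-truth activity and attenuation maps
# for the cylindrical neck calibration phantom, anthropomorphic two-lobe
# thyroid phantoms, and randomized patient-like cases.

# Narrow-beam linear attenuation coefficients at 140 keV, cm^-1.
MU_WATER_140KEV <- 0.154
MU_BONE_140KEV  <- 0.25

# Physical constants of Tc-99m.
TC99M_HALF_LIFE_S <- 21600   # 6 h nominal; exact 6.0067 h available via config

new_activity_volume <- function(activity, mu, grid, truth) {
  stopifnot(identical(dim(activity), grid$shape), identical(dim(mu), grid$shape))
  structure(list(activity = activity, mu = mu, grid = grid, truth = truth),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat(sprintf("<activity_volume> %s, A0 = %.4g MBq, grid %dx%dx%d @ %.3g mm\n",
              x$truth$kind, x$truth$a0,
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$voxel_mm[1]))
  invisible(x)
}

# Distribute a0 MBq uniformly over the voxels of a logical mask; the voxel
# sum equals a0 exactly (conservation by construction).
fill_uniform <- function(mask, a0, shape) {
  act <- array(0, shape)
  n <- sum(mask)
  if (n == 0L && a0 > 0) stop("empty source mask cannot hold activity")
  if (a0 > 0) act[mask] <- a0 / n
  act
}

# Logical mask of a z-aligned cylinder: center (cx, cy) mm, radius mm,
# axial extent [z0, z1] mm; voxel-center inclusion test.
cylinder_mask_z <- function(grid, cx, cy, radius, z0, z1) {
  xs <- axis_centers(grid$shape[1], grid$voxel_mm[1])
  ys <- axis_centers(grid$shape[2], grid$voxel_mm[2])
  zs <- axis_centers(grid$shape[3], grid$voxel_mm[3])
  inxy <- outer((xs - cx)^2, (ys - cy)^2, "+") <= radius^2
  inz <- zs >= z0 & zs <= z1
  outer(inxy, inz, "&")
}

# Logical mask of an axis-aligned ellipsoid centered at (cx, cy, cz) mm with
# semi-axes (a, b, c) mm.
ellipsoid_mask <- function(grid, cx, cy, cz, a, b, c) {
  xs <- (axis_centers(grid$shape[1], grid$voxel_mm[1]) - cx) / a
  ys <- (axis_centers(grid$shape[2], grid$voxel_mm[2]) - cy) / b
  zs <- (axis_centers(grid$shape[3], grid$voxel_mm[3]) - cz) / c
  q <- outer(xs^2, ys^2, "+")
  arr <- array(0, grid$shape)
  for (k in seq_along(zs)) arr[, , k] <- q + zs[k]^2
  arr <= 1
}

#' Cylindrical neck calibration phantom
#'
#' Builds the water-equivalent cylindrical neck phantom used for camera
#' cross-calibration: a 127 mm diameter / 127 mm height cylinder with a hot
#' cylindrical vial of approximately 15 ml whose center lies 20 mm below the
#' anterior surface. Only the vial contains activity; the surrounding
#' cylinder is cold water-equivalent material and everything outside is air.
#'
#' @param a0 Total activity in the vial at acquisition start, MBq (>= 0).
#' @param grid A [grid_spec()]; must be large enough to contain the 127 mm
#'   cylinder.
#' @param mu_water,mu_bone Linear attenuation coefficients at 140 keV in
#'   cm^-1 (bone is unused here but kept for signature symmetry).
#' @return An `activity_volume` whose `truth` record carries the total
#'   activity, the vial mask and the vial volume in ml.
#' @examples
#' ph <- make_calibration_phantom(5, grid_spec(c(40, 40, 40), 4.92))
#' sum(ph$activity)  # exactly 5 MBq
#' @export
make_calibration_phantom <- function(a0, grid,
                                     mu_water = MU_WATER_140KEV,
                                     mu_bone = MU_BONE_140KEV) {
  if (!is.finite(a0) || a0 < 0) stop("`a0` must be a non-negative activity in MBq")
  diam <- 127; height <- 127
  if (any(grid$extent_mm < c(diam, diam, height)))
    stop("grid too small to contain the 127 mm calibration cylinder")
  cx <- grid$extent_mm[1] / 2
  cy <- grid$extent_mm[2] / 2
  zmid <- grid$extent_mm[3] / 2
  body <- cylinder_mask_z(grid, cx, cy, diam / 2, zmid - height / 2, zmid + height / 2)
  # 15 ml vial: 23 mm diameter, 36.1 mm height (pi * 1.15^2 * 3.61 = 15.0 ml),
  # axis parallel to the phantom axis, center 20 mm below the anterior face.
  vial_r <- 11.5
  vial_h <- 15000 / (pi * vial_r^2)            # exact 15 ml continuous volume
  cy_ant <- cy - diam / 2                      # anterior face of the cylinder
  vial <- cylinder_mask_z(grid, cx, cy_ant + 20, vial_r,
                          zmid - vial_h / 2, zmid + vial_h / 2)
  vial <- vial & body
  mu <- array(0, grid$shape)
  mu[body] <- mu_water
  act <- fill_uniform(vial, a0, grid$shape)
  new_activity_volume(act, mu, grid, list(
    kind = "calibration_cylinder", a0 = a0,
    source_mask = vial, volume_cc = sum(vial) * voxel_ml(grid),
    depth_mm = 20
  ))
}

#' Anthropomorphic two-lobe thyroid phantom in a neck cylinder
#'
#' Builds a thyroid of the requested volume — two ellipsoidal lobes joined by
#' a cylindrical isthmus — embedded 20 mm deep (anterior) in a realistic
#' elliptical water-equivalent neck (110 mm left-right, 100 mm
#' anterior-posterior) with a simplified higher-attenuation spine insert
#' posteriorly. Activity is uniform inside the thyroid and sums to
#' `a0` exactly. The continuous (pre-voxelization) thyroid volume equals
#' `volume_cc`; the voxelized mask volume converges to it as the voxel size
#' shrinks.
#'
#' @param volume_cc Thyroid volume in cc (> 0); the five physical phantoms
#'   emulated here are 3.2, 7.5, 11.4, 19 and 30 cc.
#' @param a0 Total thyroid activity, MBq (>= 0).
#' @param grid A [grid_spec()].
#' @param mu_water,mu_bone Attenuation coefficients at 140 keV, cm^-1.
#' @return An `activity_volume`; `truth$thyroid_mask` and `truth$volume_cc`
#'   record the ground truth.
#' @examples
#' ph <- make_thyroid_phantom(19, 5, grid_spec(c(40, 40, 40), 4.92))
#' ph$truth$volume_cc
#' @export
make_thyroid_phantom <- function(volume_cc, a0, grid,
                                 mu_water = MU_WATER_140KEV,
                                 mu_bone = MU_BONE_140KEV) {
  if (!is.finite(volume_cc) || volume_cc <= 0) stop("`volume_cc` must be > 0")
  if (!is.finite(a0) || a0 < 0) stop("`a0` must be a non-negative activity in MBq")
  if (volume_cc > 100) stop("thyroid volume exceeds neck capacity")
  # realistic adult neck: elliptical cylinder, 110 mm left-right by 100 mm
  # anterior-posterior (narrower than the 127 mm calibration cylinder)
  neck_lr <- 110; neck_ap <- 100; neck_h <- 127
  if (any(grid$extent_mm < c(neck_lr, neck_ap, neck_h)))
    stop("grid too small to contain the neck phantom")
  cx <- grid$extent_mm[1] / 2
  cy <- grid$extent_mm[2] / 2
  zmid <- grid$extent_mm[3] / 2
  xs <- axis_centers(grid$shape[1], grid$voxel_mm[1])
  ys <- axis_centers(grid$shape[2], grid$voxel_mm[2])
  zs <- axis_centers(grid$shape[3], grid$voxel_mm[3])
  in_ell <- outer(((xs - cx) / (neck_lr / 2))^2,
                  ((ys - cy) / (neck_ap / 2))^2, "+") <= 1
  neck <- outer(in_ell, zs >= zmid - neck_h / 2 & zs <= zmid + neck_h / 2, "&")
  # spine: 16 mm radius bone-like cylinder, 30 mm posterior of center
  spine <- cylinder_mask_z(grid, cx, cy + 30, 16,
                           zmid - neck_h / 2, zmid + neck_h / 2) & neck

  # Thyroid geometry: two ellipsoids (semi-axes a, 0.8a, 2a) joined across a
  # ~6 mm tracheal gap by an isthmus cylinder carrying 8% of the volume.
  # Continuous volume is solved exactly; lobes and isthmus are disjoint.
  v_mm3 <- volume_cc * 1000
  v_lobe <- 0.46 * v_mm3                       # per lobe
  # (4/3) pi a * 0.8a * 2a = v_lobe  ->  a^3 = v_lobe / ((4/3) pi 1.6)
  a <- (v_lobe / ((4 / 3) * pi * 1.6))^(1 / 3)
  b <- 0.8 * a; c <- 2 * a
  isth_len <- 6                                # tracheal gap between lobe surfaces
  lobe_off <- a + isth_len / 2                 # lobe centers at +/- lobe_off
  v_isth <- 0.08 * v_mm3
  isth_r <- sqrt(v_isth / (pi * isth_len))
  cy_th <- cy - neck_ap / 2 + 20               # 20 mm deep from anterior face
  lobe1 <- ellipsoid_mask(grid, cx - lobe_off, cy_th, zmid, a, b, c)
  lobe2 <- ellipsoid_mask(grid, cx + lobe_off, cy_th, zmid, a, b, c)
  # isthmus: x-aligned cylinder between the lobes, slightly anterior
  xs <- axis_centers(grid$shape[1], grid$voxel_mm[1])
  ys <- axis_centers(grid$shape[2], grid$voxel_mm[2])
  zs <- axis_centers(grid$shape[3], grid$voxel_mm[3])
  inx <- abs(xs - cx) <= isth_len / 2
  ryz <- outer((ys - cy_th)^2, (zs - zmid)^2, "+") <= isth_r^2
  isth <- array(FALSE, grid$shape)
  for (i in which(inx)) isth[i, , ] <- ryz
  isth <- isth & !lobe1 & !lobe2
  thyroid <- (lobe1 | lobe2 | isth) & neck & !spine
  if (!any(thyroid)) stop("thyroid mask empty at this grid resolution")

  mu <- array(0, grid$shape)
  mu[neck] <- mu_water
  mu[spine] <- mu_bone
  act <- fill_uniform(thyroid, a0, grid$shape)
  new_activity_volume(act, mu, grid, list(
    kind = "anthropomorphic_thyroid", a0 = a0,
    thyroid_mask = thyroid,
    volume_cc = volume_cc,
    voxelized_volume_cc = sum(thyroid) * voxel_ml(grid),
    depth_mm = 20
  ))
}

#' Sample patient-level parameters for a synthetic cohort
#'
#' Draws the per-case quantities of a pertechnetate thyroid-uptake cohort:
#' injected activity `a_i` ~ Normal(80, 3.7^2) MBq truncated positive
#' (reference injected activity 80 MBq), true thyroid uptake uniform on
#' `tu_range` percent, thyroid volume uniform on 8-25 cc, and a Bernoulli
#' hot-nodule indicator.
#'
#' @param n Number of cases (>= 1).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @param tu_range Length-2 numeric, true-uptake interval in percent, open
#'   subset of (0, 100).
#' @param nodule_prob Probability that a case carries a hot nodule.
#' @return A data.frame with columns `case`, `a_i_mbq`, `tu_true_pct`,
#'   `volume_cc`, `has_nodule`.
#' @export
sample_cohort_params <- function(n, seed, tu_range = c(1, 12),
                                 nodule_prob = 0.5) {
  if (!is.finite(n) || n < 1) stop("`n` must be >= 1")
  if (is.null(seed) || !is.finite(seed)) stop("`seed` must be an integer")
  if (length(tu_range) != 2L || tu_range[1] <= 0 || tu_range[2] >= 100 ||
      tu_range[1] >= tu_range[2])
    stop("`tu_range` must be an increasing interval inside (0, 100)")
  if (nodule_prob < 0 || nodule_prob > 1) stop("`nodule_prob` must be in [0, 1]")
  set.seed(as.integer(seed))
  a_i <- stats::rnorm(n, mean = 80, sd = 3.7)
  while (any(a_i <= 0)) a_i[a_i <= 0] <- stats::rnorm(sum(a_i <= 0), 80, 3.7)
  data.frame(
    case = seq_len(n),
    a_i_mbq = a_i,
    tu_true_pct = stats::runif(n, tu_range[1], tu_range[2]),
    volume_cc = stats::runif(n, 8, 25),
    has_nodule = stats::runif(n) < nodule_prob
  )
}

#' Generate a synthetic patient cohort
#'
#' Builds one patient-like `activity_volume` per case from
#' [sample_cohort_params()]: a thyroid phantom of the sampled volume holding
#' `TU * A_i / 100` MBq, a diffuse extrathyroidal background (a fixed
#' fraction of the injected activity spread over the neck soft tissue,
#' emulating blood pool and salivary-type background), and, with probability
#' `nodule_prob`, a mild hot nodule (a ~1.2 cc sphere inside one lobe at
#' 1.5 times the surrounding concentration; the cohort emulates a
#' hyperthyroid population whose uptake pattern is predominantly diffuse).
#'
#' @inheritParams sample_cohort_params
#' @param grid A [grid_spec()] shared by all cases.
#' @param background_fraction Fraction of injected activity placed in the
#'   neck soft tissue (default 0.03).
#' @return A list with `params` (the parameter data.frame) and `cases` (a
#'   list of `activity_volume`, each with `truth$tu_pct` and `truth$a_i`).
#' @export
make_patient_cohort <- function(n, seed, grid, tu_range = c(1, 12),
                                nodule_prob = 0.5, background_fraction = 0.03) {
  params <- sample_cohort_params(n, seed, tu_range, nodule_prob)
  cases <- vector("list", n)
  for (k in seq_len(n)) {
    p <- params[k, ]
    a_th <- p$tu_true_pct * p$a_i_mbq / 100
    ph <- make_thyroid_phantom(p$volume_cc, a_th, grid)
    # diffuse neck background outside thyroid and spine
    soft <- ph$mu == MU_WATER_140KEV & !ph$truth$thyroid_mask
    a_bg <- background_fraction * p$a_i_mbq
    ph$activity <- ph$activity + fill_uniform(soft, a_bg, grid$shape)
    if (p$has_nodule) {
      # 1.2 cc spherical nodule in the right lobe at 1.5x concentration;
      # nodule activity is carved out of the lobe so thyroid total is kept
      set.seed(as.integer(seed) + k)
      mask <- ph$truth$thyroid_mask
      idx <- which(mask, arr.ind = TRUE)
      right <- idx[idx[, 1] < mean(idx[, 1]), , drop = FALSE]
      if (nrow(right) > 0) {
        ctr <- right[sample.int(nrow(right), 1L), ]
        ctr_mm <- (ctr - 0.5) * grid$voxel_mm
        nod <- ellipsoid_mask(grid, ctr_mm[1], ctr_mm[2], ctr_mm[3],
                              6.6, 6.6, 6.6) & mask
        if (any(nod)) {
          # base concentration solved so the thyroid total stays a_th exactly
          conc <- a_th / (sum(mask) + 0.5 * sum(nod))
          ph$activity[mask] <- conc
          ph$activity[nod] <- 1.5 * conc
          ph$activity[soft] <- a_bg / sum(soft)   # background unchanged
        }
      }
    }
    ph$truth$kind <- "patient"
    ph$truth$tu_pct <- p$tu_true_pct
    ph$truth$a_i <- p$a_i_mbq
    ph$truth$a0 <- sum(ph$activity)
    cases[[k]] <- ph
  }
  list(params = params, cases = cases)
}
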