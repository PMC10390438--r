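# End-to-end study drivers tying the stages together: camera
# cross-calibration, anthropomorphic phantom AThA recovery, and the
# synthetic patient cohort with uptake agreement and dosimetry.

#' Pipeline configuration
#'
#' One declarative object carrying every tunable of the simulated studies.
#' The defaults are the study conditions: 4.92 mm isotropic voxels on a
#' 40^3 grid (large enough for the 127 mm neck), 900 s planar acquisitions,
#' 60 x 20 s SPECT projections, OSEM 4 iterations x 6 subsets with a 1.5 mm
#' Gaussian post-filter, thresholds of 25% of Pmax for planar ROIs and 40%
#' for SPECT VOIs, and a calibration ladder of 1-20 MBq.
#'
#' @param voxel_mm Isotropic voxel size, mm.
#' @param shape Grid shape (3 integers).
#' @param planar_duration_s Planar acquisition time, s.
#' @param spect_proj_duration_s Per-projection SPECT time, s.
#' @param n_projections SPECT projections over 360 degrees.
#' @param n_heads Detector heads acquiring simultaneously.
#' @param iterations,subsets OSEM settings.
#' @param postfilter_fwhm_mm Post-reconstruction Gaussian FWHM, mm.
#' @param threshold_planar,threshold_voi Segmentation fractions of Pmax.
#' @param psf_fwhm_mm,scatter_fraction,sensitivity_cps_mbq,half_life_s
#'   Camera model, see [acq_params()].
#' @param calibration_activities Vial activity ladder, MBq.
#' @param phantom_volumes_cc Thyroid phantom volumes, cc.
#' @param phantom_concentrations Activity concentrations at which each
#'   thyroid phantom is filled, MBq/cc; activities are
#'   `concentration * volume`, spanning 0.4-10 MBq at patient-like
#'   concentrations.
#' @param cohort_n Number of synthetic patients.
#' @param tu_range True-uptake interval, percent.
#' @param nodule_prob Hot-nodule probability per case.
#' @param noise Poisson noise on (`TRUE`) or noiseless expectations.
#' @param dose_coeffs A [dose_coefficients()].
#' @param out_dir Output directory for tables/manifests, or `NULL` to skip
#'   writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_mm = 4.92,
                            shape = c(40, 40, 40),
                            planar_duration_s = 900,
                            spect_proj_duration_s = 20,
                            n_projections = 60,
                            n_heads = 2,
                            iterations = 4,
                            subsets = 6,
                            postfilter_fwhm_mm = 1.5,
                            threshold_planar = 0.25,
                            threshold_voi = 0.40,
                            psf_fwhm_mm = 3.5,
                            scatter_fraction = 0.2,
                            sensitivity_cps_mbq = 83,
                            half_life_s = TC99M_HALF_LIFE_S,
                            calibration_activities = c(1, 2, 5, 10, 15, 20),
                            phantom_volumes_cc = c(3.2, 7.5, 11.4, 19, 30),
                            phantom_concentrations = c(0.125, 0.2, 0.33),
                            cohort_n = 23,
                            tu_range = c(1, 12),
                            nodule_prob = 0.5,
                            noise = TRUE,
                            dose_coeffs = dose_coefficients(),
                            out_dir = NULL) {
  if (threshold_planar <= 0 || threshold_planar >= 1 ||
      threshold_voi <= 0 || threshold_voi >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

cfg_grid <- function(config) grid_spec(config$shape, config$voxel_mm)

cfg_planar_params <- function(config, seed) {
  acq_params("planar", duration_s = config$planar_duration_s,
             psf_fwhm_mm = config$psf_fwhm_mm,
             scatter_fraction = config$scatter_fraction,
             sensitivity_cps_mbq = config$sensitivity_cps_mbq,
             half_life_s = config$half_life_s,
             seed = if (config$noise) seed else NULL)
}

cfg_spect_params <- function(config, seed) {
  acq_params("spect", duration_s = config$spect_proj_duration_s,
             n_projections = config$n_projections,
             n_heads = config$n_heads,
             psf_fwhm_mm = config$psf_fwhm_mm,
             scatter_fraction = config$scatter_fraction,
             sensitivity_cps_mbq = config$sensitivity_cps_mbq,
             half_life_s = config$half_life_s,
             seed = if (config$noise) seed else NULL)
}

cfg_dt_tomo <- function(config) config$n_projections * config$spect_proj_duration_s

# wall-clock duration of the SPECT orbit (simultaneous heads)
cfg_wall_tomo <- function(config) cfg_dt_tomo(config) / config$n_heads

# Acquire + quantify one volume in all three modalities; returns segmented
# counts per modality (N_planar with its background term, N_AC, N_NoAC).
quantify_all_modalities <- function(vol, config, seed, background = FALSE) {
  pl <- simulate_planar(vol, cfg_planar_params(config, seed))
  roi <- segment_threshold(pl$main, config$threshold_planar)
  n_back <- if (background) background_region(pl$main, roi)$n_back else 0

  sg <- simulate_spect(vol, cfg_spect_params(config, seed + 1))
  corrected <- scatter_correct(sg$main, sg$scatter)
  rec_ac <- gaussian_postfilter(
    osem(corrected, vol$mu, config$iterations, config$subsets, config$psf_fwhm_mm),
    config$postfilter_fwhm_mm)
  rec_noac <- gaussian_postfilter(
    osem(corrected, NULL, config$iterations, config$subsets, config$psf_fwhm_mm),
    config$postfilter_fwhm_mm)
  voi_ac <- segment_threshold(rec_ac, config$threshold_voi)
  voi_noac <- segment_threshold(rec_noac, config$threshold_voi)
  list(n_planar = roi$n_roi, n_back = n_back,
       n_ac = voi_ac$n_roi, n_noac = voi_noac$n_roi)
}

#' Run the camera cross-calibration study
#'
#' Simulates the cylindrical neck calibration phantom over the configured
#' activity ladder, quantifies every level in the three modalities (Planar,
#' Tomo-AC, Tomo-NoAC) with the same threshold rule used for patients, and
#' summarizes the per-modality calibration factor (mean +/- SD) and the
#' counts-versus-activity linearity (Pearson r).
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed driving all Poisson sampling.
#' @return A list with `factors` (named list of [calibrate_modality()]
#'   results), `table` (Table-1-shaped data.frame: modality, mean, SD, r)
#'   and `per_level`.
#' @export
run_calibration <- function(config = pipeline_config(), seed = 1) {
  grid <- cfg_grid(config)
  acts <- config$calibration_activities
  if (length(acts) < 2L) stop("calibration needs at least 2 activity levels")
  res <- lapply(seq_along(acts), function(k) {
    ph <- make_calibration_phantom(acts[k], grid)
    quantify_all_modalities(ph, config, seed + 97L * k)
  })
  n_pl <- vapply(res, `[[`, 0, "n_planar")
  n_ac <- vapply(res, `[[`, 0, "n_ac")
  n_no <- vapply(res, `[[`, 0, "n_noac")
  dt_t <- cfg_dt_tomo(config)
  factors <- list(
    planar = calibrate_modality(acts, n_pl, config$planar_duration_s,
                                "Planar", config$half_life_s),
    tomo_ac = calibrate_modality(acts, n_ac, dt_t, "Tomo-AC",
                                 config$half_life_s, cfg_wall_tomo(config)),
    tomo_noac = calibrate_modality(acts, n_no, dt_t, "Tomo-NoAC",
                                   config$half_life_s, cfg_wall_tomo(config))
  )
  tab <- do.call(rbind, lapply(factors, function(f)
    data.frame(modality = f$fcal$modality, fcal_mean = f$fcal$value,
               fcal_sd = f$fcal$sd, linearity_r = f$r)))
  rownames(tab) <- NULL
  per_level <- data.frame(a0 = acts, n_planar = n_pl, n_tomo_ac = n_ac,
                          n_tomo_noac = n_no)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_pair(tab, file.path(config$out_dir, "calibration_factors"))
    write_table_pair(per_level, file.path(config$out_dir, "calibration_ladder"))
    write_manifest(config, seed, config$out_dir, "calibration")
  }
  list(factors = factors, table = tab, per_level = per_level)
}

#' Run the anthropomorphic phantom AThA recovery study
#'
#' Simulates every configured thyroid volume at every configured activity,
#' estimates AThA in the three modalities with the supplied calibration
#' factors, and reports per-case relative percentage differences and the
#' per-modality Pearson correlation between estimated and theoretical AThA.
#'
#' @param config A [pipeline_config()].
#' @param calibration Output of [run_calibration()].
#' @param seed Integer seed.
#' @return A list with `table` (per-case estimates and relative
#'   differences) and `summary` (per-modality mean/SD of the relative
#'   difference and estimated-vs-theoretical r).
#' @export
run_phantom_study <- function(config = pipeline_config(), calibration,
                              seed = 1) {
  if (missing(calibration) || is.null(calibration$factors))
    stop("calibration output is required before the phantom study")
  grid <- cfg_grid(config)
  dt_t <- cfg_dt_tomo(config)
  cases <- expand.grid(volume_cc = config$phantom_volumes_cc,
                       conc = config$phantom_concentrations)
  cases$a0 <- cases$volume_cc * cases$conc
  rows <- lapply(seq_len(nrow(cases)), function(k) {
    ph <- make_thyroid_phantom(cases$volume_cc[k], cases$a0[k], grid)
    q <- quantify_all_modalities(ph, config, seed + 131L * k)
    data.frame(
      volume_cc = cases$volume_cc[k],
      atha_true = cases$a0[k],
      atha_planar = estimate_atha(q$n_planar, calibration$factors$planar$fcal,
                                  config$planar_duration_s),
      atha_tomo_ac = estimate_atha(q$n_ac, calibration$factors$tomo_ac$fcal, dt_t),
      atha_tomo_noac = estimate_atha(q$n_noac, calibration$factors$tomo_noac$fcal,
                                     dt_t)
    )
  })
  tab <- do.call(rbind, rows)
  for (m in c("planar", "tomo_ac", "tomo_noac"))
    tab[[paste0("rpd_", m)]] <-
      relative_percent_difference(tab[[paste0("atha_", m)]], tab$atha_true)
  summary <- do.call(rbind, lapply(c("planar", "tomo_ac", "tomo_noac"),
    function(m) {
      est <- tab[[paste0("atha_", m)]]
      data.frame(modality = m,
                 mean_rpd = mean(tab[[paste0("rpd_", m)]]),
                 sd_rpd = stats::sd(tab[[paste0("rpd_", m)]]),
                 r = pearson(est, tab$atha_true)$r)
    }))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_pair(tab, file.path(config$out_dir, "phantom_atha"))
    write_table_pair(summary, file.path(config$out_dir, "phantom_summary"))
    write_manifest(config, seed, config$out_dir, "phantom_study")
  }
  list(table = tab, summary = summary)
}

#' Run the synthetic patient cohort study
#'
#' Generates a seeded cohort of patient-like volumes, measures thyroid
#' uptake per case in the three modalities (background-corrected for
#' planar), computes pairwise modality agreement (Pearson + Bland-Altman)
#' and per-case radiation doses (CTDIvol and DLP drawn around the reference
#' examination values), and merges everything into one report.
#'
#' @param config A [pipeline_config()].
#' @param calibration Output of [run_calibration()].
#' @param seed Integer seed.
#' @return A list with `tu_table` (per-case truth and estimated TU),
#'   `agreement` ([modality_agreement()] table), `doses` (per-case dose
#'   data.frame) and `report` (merged list, also written as JSON when
#'   `config$out_dir` is set).
#' @export
run_cohort_study <- function(config = pipeline_config(), calibration,
                             seed = 1) {
  if (missing(calibration) || is.null(calibration$factors))
    stop("calibration output is required before the cohort study")
  grid <- cfg_grid(config)
  dt_t <- cfg_dt_tomo(config)
  cohort <- make_patient_cohort(config$cohort_n, seed, grid,
                                tu_range = config$tu_range,
                                nodule_prob = config$nodule_prob)
  rows <- lapply(seq_len(config$cohort_n), function(k) {
    vol <- cohort$cases[[k]]
    q <- quantify_all_modalities(vol, config, seed + 211L * k,
                                 background = TRUE)
    a_i <- vol$truth$a_i
    data.frame(
      case = k,
      a_i_mbq = a_i,
      tu_true = vol$truth$tu_pct,
      planar = thyroid_uptake(q$n_planar, q$n_back,
                              calibration$factors$planar$fcal, a_i,
                              config$planar_duration_s, "Planar")$tu,
      tomo_ac = thyroid_uptake(q$n_ac, 0, calibration$factors$tomo_ac$fcal,
                               a_i, dt_t, "Tomo-AC")$tu,
      tomo_noac = thyroid_uptake(q$n_noac, 0,
                                 calibration$factors$tomo_noac$fcal,
                                 a_i, dt_t, "Tomo-NoAC")$tu
    )
  })
  tu_table <- do.call(rbind, rows)
  agreement <- modality_agreement(tu_table)
  set.seed(as.integer(seed) + 999L)
  ctdi <- pmax(stats::rnorm(config$cohort_n, 2.21, 0.2), 0.1)
  dlp <- pmax(stats::rnorm(config$cohort_n, 49.5, 9), 1)
  doses <- do.call(rbind, lapply(seq_len(config$cohort_n), function(k) {
    r <- dose_report(tu_table$a_i_mbq[k], ctdi[k], dlp[k], config$dose_coeffs)
    data.frame(case = k, a_i_mbq = tu_table$a_i_mbq[k],
               ctdi_vol_mgy = ctdi[k], dlp_mgycm = dlp[k],
               e_nm_msv = r$e_nm_msv, d_thyroid_nm_mgy = r$d_thyroid_nm_mgy,
               e_ct_msv = r$e_ct_msv, d_thyroid_ct_mgy = r$d_thyroid_ct_mgy)
  }))
  report <- list(n = config$cohort_n, seed = seed,
                 tu = tu_table, agreement = agreement, doses = doses)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_pair(tu_table, file.path(config$out_dir, "cohort_tu"))
    write_table_pair(agreement, file.path(config$out_dir, "cohort_agreement"))
    write_table_pair(doses, file.path(config$out_dir, "cohort_doses"))
    jsonlite::write_json(report, file.path(config$out_dir, "cohort_report.json"),
                         dataframe = "columns", digits = NA)
    write_manifest(config, seed, config$out_dir, "cohort_study")
  }
  list(tu_table = tu_table, agreement = agreement, doses = doses,
       report = report)
}
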