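# Independent oracles and small hand-built fixtures used across the suite.

# Construct a bare activity/attenuation volume without the phantom
# generators, for controlled physics tests.
raw_volume <- function(activity, mu, voxel_mm) {
  grid <- grid_spec(dim(activity), voxel_mm)
  structure(list(activity = activity, mu = mu, grid = grid,
                 truth = list(kind = "raw", a0 = sum(activity))),
            class = "activity_volume")
}

raw_planar <- function(counts, pixel_mm = c(1, 1), duration_s = 1) {
  structure(list(counts = counts, pixel_mm = pixel_mm,
                 duration_s = duration_s, window = "main"),
            class = "planar_image")
}

# Brute-force connected component containing `seed` (flat index) with
# king-move connectivity, by explicit stack-based flood fill over
# coordinates; independent of the package's dilation-based implementation.
flood_fill_component <- function(mask, seed) {
  d <- dim(mask)
  nd <- length(d)
  comp <- array(FALSE, d)
  stack <- list(arrayInd(seed, d)[1, ])
  comp[seed] <- TRUE
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      qi <- matrix(q, 1)
      if (mask[qi] && !comp[qi]) {
        comp[qi] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  comp
}

# Decay-averaged activity by numerical quadrature of the defining integral.
decay_quadrature <- function(a0, dt, half_life) {
  lam <- log(2) / half_life
  a0 * stats::integrate(function(t) exp(-lam * t), 0, dt,
                        rel.tol = 1e-12)$value / dt
}

# Small, fast pipeline configuration reused by determinism/pipeline tests.
tiny_config <- function(...) {
  pipeline_config(shape = c(32, 32, 32),
                  calibration_activities = c(2, 10),
                  phantom_volumes_cc = c(7.5, 19),
                  phantom_concentrations = c(0.2, 0.33),
                  cohort_n = 3, ...)
}

# Memoized full-condition calibration shared by the acceptance tests.
.acc_cache <- new.env(parent = emptyenv())
acceptance_calibration <- function(seed = 101) {
  key <- paste0("cal", seed)
  if (is.null(.acc_cache[[key]]))
    .acc_cache[[key]] <- run_calibration(pipeline_config(), seed = seed)
  .acc_cache[[key]]
}
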