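#!/usr/bin/env Rscript
# Cross-calibration of the simulated camera against the cylindrical neck
# phantom: a 1-20 MBq activity ladder is acquired in planar and SPECT
# (reconstructed with and without attenuation correction), segmented with
# the same percent-of-max rule used for patients, and summarized as a
# per-modality calibration factor with its linearity.
#
# Writes: results/calibration_factors.{csv,json},
#         results/calibration_ladder.{csv,json}, a stage manifest, and
#         results/calibration.rds consumed by the downstream stages.

library(thyroquant)

seed <- 1
cfg <- pipeline_config(out_dir = "results")
cal <- run_calibration(cfg, seed = seed)

cat("Cross-calibration factors (counts per MBq s in each modality's units):\n")
print(cal$table, row.names = FALSE)
cat(sprintf("\nPlanar factor lands at %.1f counts/(MBq s); linearity r >= %.6f\n",
            cal$table$fcal_mean[1], min(cal$table$linearity_r)))
cat("Attenuation correction raises the tomographic factor, as expected:",
    sprintf("%.3f (Tomo-AC) vs %.3f (Tomo-NoAC)\n",
            cal$table$fcal_mean[2], cal$table$fcal_mean[3]))

saveRDS(list(config = cfg, seed = seed, calibration = cal),
        file.path("results", "calibration.rds"))
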