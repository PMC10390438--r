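#!/usr/bin/env Rscript
# Absolute thyroid activity (AThA) recovery on the five anthropomorphic
# thyroid phantoms (3.2-30 cc), each filled at three patient-like
# concentrations spanning 0.4-10 MBq, quantified in planar, Tomo-AC and
# Tomo-NoAC with the calibration factors from stage 01.
#
# Writes: results/phantom_atha.{csv,json}, results/phantom_summary.{csv,json}.

library(thyroquant)

stage1 <- readRDS(file.path("results", "calibration.rds"))
ps <- run_phantom_study(stage1$config, stage1$calibration, seed = stage1$seed + 1)

cat("Estimated vs theoretical AThA, relative percentage difference:\n")
print(ps$summary, row.names = FALSE)
cat("\nPer-case table written to results/phantom_atha.csv;",
    "the attenuation-corrected chain recovers the injected activity",
    sprintf("within %.1f%% on average, while skipping attenuation",
            ps$summary$mean_rpd[ps$summary$modality == "tomo_ac"]),
    sprintf("correction biases it by %+.1f%%.\n",
            ps$summary$mean_rpd[ps$summary$modality == "tomo_noac"]))

saveRDS(ps, file.path("results", "phantom_study.rds"))
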