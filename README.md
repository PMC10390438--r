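# thyroquant

Quantitative thyroid scintigraphy on simulated planar and SPECT images.

Thyroid uptake (TU) — the percentage of an injected
⁹⁹ᵐTc-pertechnetate activity localized in the thyroid — and absolute
thyroid activity (AThA) can be measured on a gamma camera once the
camera is cross-calibrated against a phantom of known activity:

    F_cal = N_ROI / (A_acq · Δt)                    counts/(MBq·s)
    AThA  = N_ROI,th / (F_cal · Δt)                 MBq
    TU(%) = (N_ROI,th − N_back) / (F_cal · Δt · A_i) · 100

with `A_acq` the decay-averaged phantom activity over the acquisition,
`A_i` the net injected activity, and regions segmented automatically at
a fixed fraction of the count maximum Pmax (25% for planar ROIs, 40%
for SPECT VOIs; background subtraction for planar only). This package
implements that whole chain for three modalities — Planar, SPECT with
CT-based attenuation correction (Tomo-AC) and without (Tomo-NoAC) —
together with a synthetic phantom-and-camera simulator (attenuated
parallel-beam projector, detector PSF, dual-energy-window scatter,
Poisson noise, OSEM reconstruction with resolution recovery), so every
quantity is verifiable against ground truth without any camera data. It
is aimed at medical physicists and methodologists who want a tested,
transparent reference implementation of percent-of-max thyroid
quantification and its failure modes.

## Worked example

Cross-calibrate the simulated camera on the cylindrical neck phantom
(15 ml vial, 20 mm deep), then measure a 19 cc thyroid phantom holding
5 MBq:

```r
library(thyroquant)

cfg <- pipeline_config()            # 4.92 mm voxels, clinical protocol
cal <- run_calibration(cfg, seed = 1)
cal$table
#>    modality  fcal_mean     fcal_sd linearity_r
#>      Planar 66.0265169 0.153393320   0.9999990
#>     Tomo-AC  1.3472575 0.013853975   0.9999867
#>   Tomo-NoAC  0.6477842 0.009744764   0.9999881
```

The planar factor sits at 66.0 counts/(MBq·s) with counts essentially
proportional to activity across the 1–20 MBq ladder (r ≥ 0.99998), and
attenuation correction roughly doubles the tomographic factor — the
uncorrected reconstruction recovers fewer counts because it leaves
photon attenuation uncompensated. (Tomographic factors are in the
reconstruction's own count units, so only their ordering is
meaningful.)

```r
ps <- run_phantom_study(cfg, cal, seed = 2)
ps$summary
#>    modality   mean_rpd    sd_rpd         r
#>      planar  0.8462636 3.0537828 0.9997509
#>     tomo_ac -4.1868490 0.9485228 0.9999403
#>   tomo_noac  3.0841563 1.2936625 0.9998097
```

Across five anthropomorphic thyroids (3.2–30 cc) at patient-like
concentrations, the attenuation-corrected chain recovers the injected
activity to −4.2% on average and the planar chain to +0.8%, with
estimated-vs-true correlation above 0.999 in every modality.

```r
co <- run_cohort_study(cfg, cal, seed = 3)
max(abs(co$tu_table$planar - co$tu_table$tu_true))   # 0.54 uptake points
co$agreement$r                                       # 0.998 0.998 1.000

dose_report(79.2, 2.21, 49.5)
#> <dose_report> effective: 0.95 (NM) + 0.34 (CT) mSv; thyroid: 1.74 (NM) + 3.88 (CT) mGy
```

On a seeded 23-patient synthetic cohort (true TU 1–12%), recovered
uptake stays within ~0.6 uptake points of truth in both planar and
Tomo-AC, the three modality pairs agree with r ≥ 0.99, and the dose
block reproduces the reference examination: a ~1.3 mSv effective dose
of which the CT contributes a quarter, but most of the thyroid organ
dose.

## Analysis workflow

The `analysis/` directory holds the campaign as numbered drivers over
the package functions; each prints what it found and writes its tables
(CSV + JSON, with run manifests) under `results/`:

```sh
Rscript analysis/01_calibration.R     # camera cross-calibration + linearity
Rscript analysis/02_phantom_study.R   # AThA recovery on 5 thyroid phantoms
Rscript analysis/03_cohort_study.R    # 23-patient TU cohort + agreement + doses
Rscript analysis/04_dosimetry.R       # reference dosimetry worked example
```

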