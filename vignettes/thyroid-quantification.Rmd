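---
title: "Quantitative thyroid scintigraphy on simulated planar and SPECT images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative thyroid scintigraphy on simulated planar and SPECT images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thyroid uptake (TU) — the fraction of an injected
^99m^Tc-pertechnetate activity that localizes in the thyroid — is a
routine functional measurement in the work-up of hyperthyroidism.
Classically it is read off an anterior planar scintigram; modern
large-field CZT cameras also permit SPECT and SPECT/CT acquisitions
centred on the neck, which add depth information and CT-based
attenuation correction at the cost of extra radiation exposure. The
quantification chain in all three cases is the same:

1. **Cross-calibration.** A phantom of known activity converts image
   counts to activity. The cross-calibration factor in counts/(MBq s) is

   $$F_\mathrm{cal} = \frac{N_\mathrm{ROI}}{A_\mathrm{acq}\,\Delta t},$$

   where $N_\mathrm{ROI}$ is the segmented phantom-vial counts,
   $\Delta t$ the acquisition duration, and $A_\mathrm{acq}$ the
   decay-averaged vial activity,
   $A_\mathrm{acq} = A_0\,(1 - e^{-\lambda \Delta t})/(\lambda \Delta t)$
   with $\lambda = \ln 2 / T_{1/2}$.

2. **Segmentation.** Regions are grown automatically from the count
   maximum $P_\mathrm{max}$: every pixel/voxel at or above a fixed
   fraction of $P_\mathrm{max}$ belongs to the region, and the connected
   component containing the maximum is kept (8-connectivity in 2-D,
   26-connectivity in 3-D). The standard fractions are 25 % for planar
   ROIs and 40 % for SPECT VOIs.

3. **Quantification.** Absolute thyroid activity and uptake follow by
   inverting the calibration relation:

   $$\mathrm{AThA} = \frac{N_\mathrm{ROI,th}}{F_\mathrm{cal}\,\Delta t},
   \qquad
   \mathrm{TU}\,(\%) = \frac{N_\mathrm{ROI,th} - N_\mathrm{back}}
   {F_\mathrm{cal}\,\Delta t\,A_i} \times 100,$$

   with $A_i$ the net injected activity (full minus empty syringe) and
   $N_\mathrm{back}$ an area-scaled background term used for planar
   images only. Note the explicit $\Delta t$ in the uptake formula: the
   ratio $N/(F_\mathrm{cal} A_i)$ alone carries units of seconds, so the
   division by $\Delta t$ is required for TU to be dimensionless and
   consistent with the calibration and AThA relations. This is a
   deliberate dimensional-consistency choice.

Because no public image data exist for this examination, the package
pairs the quantification chain with a synthetic phantom-and-camera
simulator, so that every stage can be validated against known ground
truth, end to end.

## The simulator

### Phantoms

* `make_calibration_phantom()` — the cylindrical neck calibration
  phantom: a water-equivalent cylinder of 127 mm diameter and height
  containing a hot cylindrical vial of exactly 15 ml (23 mm diameter)
  whose centre lies 20 mm below the anterior surface, the thyroid depth
  of an average adult. Only the vial is radioactive.
* `make_thyroid_phantom()` — an anthropomorphic thyroid of requested
  volume: two ellipsoidal lobes (semi-axis ratio $a : 0.8a : 2a$)
  carrying 92 % of the volume, joined across a 6 mm tracheal gap by a
  cylindrical isthmus carrying 8 %. The continuous volume is solved
  exactly, so the voxelized volume converges to the request as the
  voxel size shrinks. The gland sits 20 mm deep in a realistic
  elliptical neck (110 mm left-right × 100 mm anterior-posterior) with
  a bone-like spine insert. The neck being narrower than the 127 mm
  calibration cylinder matters: without attenuation correction, thyroid
  counts are *less* attenuated than the calibration vial's, which is
  what makes the uncorrected reconstruction overestimate activity.
* `make_patient_cohort()` — seeded patient-like cases: injected
  activity $A_i \sim N(80, 3.7^2)$ MBq truncated positive, true uptake
  uniform on a configurable interval (default 1–12 %), thyroid volume
  uniform on 8–25 cc, thyroid activity $\mathrm{TU} \cdot A_i / 100$,
  plus a diffuse extrathyroidal background (3 % of $A_i$ in the neck
  soft tissue, emulating blood pool) and, with probability 0.5, a mild
  hot nodule (1.2 cc at 1.5× the surrounding concentration).

Attenuation maps contain only air (0), water (0.154 cm⁻¹) and
bone-like (0.25 cm⁻¹) values — standard narrow-beam coefficients at
140 keV.

### Acquisition

The camera model is deliberately at the physics level, not the
transport level: attenuated parallel-beam projection
(voxel emissions weighted by $e^{-\int \mu\,dl}$ along their ray),
a Gaussian detector PSF, an additive broad scatter component, and
Poisson counting noise. Two parameters summarize the detector:

* **Effective sensitivity** $\varepsilon$ = 83 counts/(MBq s),
  calibrated once so the simulated planar cross-calibration factor
  lands near the 66 counts/(MBq s) measured for a large-field CZT
  camera at 140 keV with this phantom.
* **Effective PSF FWHM** = 3.5 mm, the end-to-end resolution of the
  chain *including* vendor resolution-recovery reconstruction and
  post-processing. It was calibrated against the reported recovery
  behaviour of the attenuation-corrected chain on anthropomorphic
  phantoms (mean relative difference of estimated vs true activity
  within a few percent); the recovery response is flat below about
  4 mm, so the exact value is not load-bearing. Collimator septa, CZT
  pixel structure and depth-dependent resolution are not modeled.

Planar acquisitions are anterior views of 900 s with a
140 keV ± 10 % main window. SPECT acquisitions are 60 projections of
20 s over 360°, acquired by two opposed heads simultaneously (30
angular steps, 600 s wall time); radioactive decay is applied per
angular step, and the planar chain uses the closed-form decay average.
The half-life defaults to the nominal 6 h of ^99m^Tc (21600 s; the
exact 6.0067 h is a parameter).

Scatter is modeled as a spatially broadened additive term: a 30 mm
FWHM Gaussian blur of the primary image scaled by a scatter fraction
(default 0.2) is added to the main window, and a fixed share of it is
recorded in the 120 keV ± 5 % scatter window. The dual-energy-window
subtraction factor defaults to $k = 1.1$ scaled by the
main-to-scatter window-width ratio (21/12 keV), and the generator's
scatter-window share is set to $1/k$, so the subtraction is unbiased
in expectation *for this synthetic scatter model*. This is a
generator-side convention, not a claim about clinical scatter physics.

### Reconstruction

`osem()` implements ordered-subsets expectation maximization with a
rotation-based projector: 4 iterations × 6 subsets by default, the
protocol used clinically. Attenuation correction uses the phantom's
ground-truth μ-map (perfect registration — CT simulation and
misregistration are out of scope); resolution recovery is realized by
modeling the PSF inside the projector. Scatter correction is
dual-energy-window subtraction clipped at zero, applied to the
sinogram before reconstruction. A separable Gaussian post-filter of
1.5 mm FWHM (the clinical protocol value) is applied after
reconstruction; at 4.92 mm voxels its effect is minor. The
backprojector is the image-rotation adjoint of the projector — the
standard rotate-based construction, whose projector/backprojector
consistency is verified by a noiseless total-counts test rather than
by exact matrix transposition.

Reconstructed volumes are in "count units": the reconstruction's
forward projections match the sinogram. Their absolute scale is
arbitrary (vendor-specific in real systems), which is why tomographic
calibration-factor *magnitudes* are not comparable across
implementations — only the ordering
$F_\mathrm{cal}(\mathrm{Tomo\text{-}NoAC}) <
F_\mathrm{cal}(\mathrm{Tomo\text{-}AC})$ is a physical statement, and
it is asserted in the tests.

## Study conditions

The three study drivers reproduce the structure of a full examination
campaign, at desk scale:

* `run_calibration()` — calibration ladder of
  {1, 2, 5, 10, 15, 20} MBq, all three modalities, reporting the
  per-modality factor (mean ± SD) and counts-vs-activity Pearson r.
* `run_phantom_study()` — five thyroid volumes
  {3.2, 7.5, 11.4, 19, 30} cc, each filled at three patient-like
  concentrations {0.125, 0.2, 0.33} MBq/cc, spanning 0.4–9.9 MBq.
  Activities scale with gland volume because the phantom campaign this
  emulates chose activities representing typical patient thyroid
  uptake; a fixed low activity in a large gland (e.g. 0.4 MBq in
  30 cc, an order of magnitude below clinical concentration) is a
  regime in which percent-of-max segmentation provably degenerates —
  the count maximum of a noisy reconstruction is biased upward, the
  threshold rises with it, and the VOI collapses.
* `run_cohort_study()` — 23 seeded synthetic patients, per-case TU in
  the three modalities, pairwise agreement (Pearson +
  Bland–Altman with mean ± 2 sample SD limits), and per-case doses
  with CTDIvol ~ N(2.21, 0.2²) mGy and DLP ~ N(49.5, 9²) mGy cm.

All simulations run on a 40³ grid of 4.92 mm isotropic voxels — the
clinical SPECT voxel size, on a field of view that comfortably
contains the phantoms. These sizes keep a full three-stage campaign
(6 calibration levels + 15 phantom cases + 23 patients, each with a
planar simulation, a SPECT simulation and two reconstructions) in the
minutes range on one CPU; they are the package's chosen problem
sizes, stated here so results are read at the scale they were
computed.

## Dosimetry

`nm_doses()` and `ct_doses()` are linear coefficient models:

* Pertechnetate: thyroid dose 0.022 mGy/MBq (the published adult
  intravenous-pertechnetate organ coefficient) and effective dose
  0.012 mSv/MBq. The latter is reverse-engineered from the reference
  examination of the emulated study (0.95 mSv at 79.2 MBq) and
  differs from some published tabulations; it is a declared
  calibration, not an endorsement of a coefficient.
* CT: effective dose per DLP (0.34/49.5 mSv per mGy cm) and thyroid
  dose per CTDIvol (3.88/2.21 mGy/mGy), both fitted to the same
  reference examination. The Monte-Carlo organ-dosimetry software used
  clinically is proprietary; these linear factors replace it and are
  configurable.

Consequently the CT coefficients *reproduce* their calibration point
by construction — the tests treat that as an arithmetic check of the
linear model, not as independent validation.

## Numerical choices

* Thresholds are inclusive (≥, not >), so plateau ties are kept.
* Negative net counts (background exceeding the thyroid ROI) are
  clipped to zero with a warning, keeping TU in [0, 100].
* Dual-energy-window subtraction clips at zero per bin, as OSEM
  requires non-negative data.
* OSEM guards divisions with a 10⁻¹² floor; an all-zero sinogram is a
  fixed point and returns an all-zero volume.
* The Gaussian kernels are column-normalized, so smoothing
  redistributes every voxel's counts exactly; interior totals are
  preserved to well under 0.1 %.
* The decay average uses `expm1` to avoid cancellation for very short
  acquisitions.
* Background ROIs are rectangles of the thyroid ROI's x-extent placed
  one pixel caudal to it, with the summed counts rescaled to the
  thyroid ROI's pixel count — the conventional area-normalized
  background subtraction; the source publication did not specify the
  background geometry.

## What the tests do and do not show

The simulator and the quantification chain share the voxel grid and
the attenuation/PSF/scatter models ("inverse crime"): reconstruction
operates under exactly the physics that generated the data. The test
suite therefore validates the *quantification logic* — calibration
consistency, segmentation, activity and uptake recovery, agreement
statistics, dose arithmetic — not detector transport or the
robustness of percent-of-max segmentation to model mismatch. Known
limitations, deliberate:

* No collimator/septal modeling, no depth-dependent resolution, no
  energy-resolved scatter; the camera is two effective parameters.
* Perfectly registered, noise-free attenuation maps.
* Percent-of-max segmentation assumes a predominantly diffuse uptake
  pattern. Strongly focal patterns (intense hot nodules) raise
  $P_\mathrm{max}$ and shrink the region toward the nodule,
  underestimating whole-gland counts — differently in 2-D and 3-D.
  The synthetic cohort therefore carries only mild focal
  heterogeneity; quantifying predominantly nodular glands with this
  method is out of the validated envelope.
* Patient cases are imaged at one time point; the 20 min delay
  between injection and imaging is not modeled (truth uptake is
  defined at acquisition start).
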