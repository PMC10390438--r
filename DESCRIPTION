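Package: thyroquant
Title: Quantitative Thyroid Scintigraphy on Simulated Planar and SPECT Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for quantitative thyroid scintigraphy with
    Tc-99m pertechnetate: cross-calibration of a gamma camera against a
    cylindrical neck phantom, percent-of-maximum threshold segmentation,
    absolute thyroid activity and thyroid uptake estimation on planar and
    SPECT images (with and without attenuation correction), agreement
    statistics (Pearson, Bland-Altman), and coefficient-based internal
    dosimetry. All stages are driven by a synthetic phantom and camera
    simulator (attenuated parallel-beam projector, dual-energy-window
    scatter, Poisson counting noise, OSEM reconstruction) so that every
    quantity is verifiable against known ground truth without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
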