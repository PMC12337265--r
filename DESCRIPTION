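Package: mregpulse
Title: Voxel-Wise Physiological Brain Pulsation Biometrics for Fast fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping physiological brain pulsations in fast fMRI
    (MREG) time series sampled at 10 Hz. Computes voxel-wise coefficient of
    variation, band spectral power and normalized Shannon spectral entropy in
    the vasomotor (very-low-frequency), respiratory and cardiac bands;
    subject-level preprocessing and motion quality control; permutation-based
    group inference with threshold-free cluster enhancement and
    Freedman-Lane nuisance handling; mutual-difference-mask ROC analysis;
    heart-rate-variability RMSSD from photoplethysmogram beat detection; and
    synthetic generators (cohort, pulsatile-flow phantom, PPG) with known
    ground truth so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
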