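Package: prfval
Title: Parameter-Recovery Validation for Population Receptive Field Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and parameter-recovery validation for
    population receptive field (pRF) mapping with fMRI. Generates bar-sweep
    and randomized visual stimulus apertures, synthesizes BOLD time series
    from Gaussian and difference-of-Gaussians receptive fields through
    hemodynamic response function (HRF) convolution with parameterized white,
    physiological and drift noise, fits the circular Gaussian linear pRF
    model by grid search plus bounded nonlinear refinement, and reports
    estimate-versus-truth accuracy including HRF-mismatch bias matrices,
    coverage ellipses and noise-calibration utilities for on/off block
    designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
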