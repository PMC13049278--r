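Package: mpftherm
Title: Model Predictive Filtering for MR Temperature Imaging of Laser Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accelerated proton-resonance-frequency (PRF) MR thermometry for
    laser interstitial thermal therapy (LITT). Estimates a treatment-specific
    deposited-power map Q from a low-power calibration heating by Green's
    function inversion of the Pennes bioheat equation, forward-predicts the
    treatment heating with a spectral exponential-integrator solver, and uses
    the predicted k-space to supplement retrospectively subsampled Cartesian
    acquisitions (model predictive filtering). Includes CEM43 thermal
    dosimetry, Dice overlap and hottest-voxel evaluation metrics, sampling
    mask generators (segmented-EPI kz-inside-ky and pseudo-Gaussian), and a
    digital phantom generator with calibrated complex Gaussian noise so the
    whole pipeline runs without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown, withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
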