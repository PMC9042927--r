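Package: wfmap
Title: Wide-Field Intrinsic-Signal Mapping with Phase Encoding and Photon
    Transport Resolution Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for through-skull wide-field intrinsic-signal
    optical imaging. Implements phase-encoded Fourier mapping of periodic
    sensory stimulation (tonotopy, retinotopy, somatotopy, multi-modality
    parcellation), hemodynamic-delay estimation by combining temporally
    mirrored session pairs, HSV/RGB tuning-map rendering with landmark-based
    affine co-registration, trial-based category statistics (Welch t maps,
    differential maps), a layered-tissue perturbation Monte Carlo that
    predicts the lateral resolution of through-skull signals, and a
    complex-plane diffusion scan that compares maps acquired at different
    effective resolutions. A synthetic-movie generator with planted per-pixel
    tuning, delay, polarity and noise provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    jsonlite,
    tiff,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
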