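Package: iasmeg
Title: Hierarchical Bayesian Source Reconstruction for M/EEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of neural current dipole activity from
    magnetoencephalography (MEG) or electroencephalography (EEG) sensor data
    by an iterative alternating sequential (IAS) algorithm. The solver
    computes the joint maximum a posteriori estimate of dipole moments and
    their variances under a conditionally Gaussian hierarchical prior with a
    gamma hyperprior, alternating a priorconditioned conjugate-gradient
    least-squares (CGLS) dipole update with a closed-form variance update.
    Anatomical orientation priors, automatic sensitivity (depth) weighting
    driven by a single signal-to-noise-ratio input, warm-started time-series
    processing, a spherical-head synthetic data generator for validation,
    and sliced (axial/coronal/sagittal) activity-map visualization are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
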