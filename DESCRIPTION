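Package: pcct
Title: Statistical Iterative Reconstruction for Grating-Based X-Ray
    Phase-Contrast Computed Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for grating-based
    (Talbot-Lau) X-ray phase-contrast computed tomography. Provides a
    phase-stepping interferometer simulator with Poisson counting noise
    and differential-phase wrapping, weighted least-squares stepping-curve
    signal extraction with delta-method variance propagation, parallel-beam
    forward/back projectors with exact adjoints, Ram-Lak and Hilbert-filter
    filtered backprojection baselines, an absorption-derived bone-prior
    weight modification that suppresses phase-wrapping streak artifacts,
    and a penalized weighted least-squares statistical iterative
    reconstruction (SIR) solved by nonlinear conjugate gradients with
    quadratic, edge-preserving Huber, and bone-coupling regularization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
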