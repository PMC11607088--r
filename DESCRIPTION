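Package: aoloop
Title: Adaptive Optics Control-Loop Theory, Simulation, and Shack-Hartmann
    Wavefront Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytic and simulation tools for closed-loop adaptive optics
    (AO) as used in ophthalmic imaging. Implements the rejection and noise
    transfer functions of an integral-controller AO loop, a transcendental
    bandwidth equation and its numerical solution, a discrete-event
    simulator of continuous- and discontinuous-exposure AO timing schemes,
    a Shack-Hartmann wavefront sensor forward model with thresholded
    center-of-gravity centroiding and Zernike least-squares reconstruction,
    a deformable-mirror modal controller built by singular-value
    decomposition of an influence-function matrix, generators for pink-noise
    stimuli and power-law ocular-aberration spectra, and power-spectral-
    density machinery for measuring empirical rejection curves and
    predicting the loop rate required for diffraction-limited correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
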