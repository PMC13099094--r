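Package: retinasc
Title: Spatial-Contrast Encoding Models for Retinal Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Retina", "Modeling Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling how retinal ganglion cells encode
    spatiotemporal visual stimuli. Generates checkerboard white noise,
    reversing gratings, and surrogate naturalistic movies with simulated
    saccades and fixational eye movements; simulates ground-truth
    rectified-subunit model cells with Poisson spiking; estimates receptive
    fields by spike-triggered averaging with elliptical Gaussian fits; fits
    linear-nonlinear (LN) and spatial-contrast (SC) encoding models by
    Poisson maximum likelihood; infers spatial subunits via spike-triggered
    covariance and a logical-OR model with regularized gradient training;
    and computes response statistics including the reversing-grating index,
    local-spatial-contrast sensitivity, radially averaged power spectra,
    and cell-type feature clustering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
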