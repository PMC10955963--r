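Package: scatterct
Title: Scatter-Radiation Computational Ghost Imaging and Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for X-ray scatter
    computational ghost imaging (CGI) computed tomography. Generates
    structured binary illumination patterns from a large physical mask
    model, simulates single-pixel bucket signals from voxel phantoms
    under a single-scatter Compton (Klein-Nishina) forward model with
    Beer-Lambert attenuation, recovers per-angle scatter images by
    solving Ax = S with linear solvers, a proximal total-variation
    solver, and a self-supervised untrained-network solver with a
    total-variation constraint, assembles 3D tomograms with SART-TV
    under parallel-beam geometry, and estimates resolution by Fourier
    ring correlation against the half-bit threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
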