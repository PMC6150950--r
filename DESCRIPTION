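Package: megres
Title: Spatial Resolution of MEG Beamformer Source Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and optimise the spatial resolution of
    linearly constrained minimum variance (LCMV) beamformer source
    reconstruction for magnetoencephalography (MEG). Provides a spherical
    conductor dipole forward model (Sarvas closed form, single or multiple
    local spheres), simulation of epoched sensor data from pairs of closely
    spaced cortical dipoles with Gaussian or phase-randomised surrogate
    noise, three covariance-segmentation beamformer strategies with pseudo-z
    and pseudo-t imaging, an 80%-dip two-peak resolvability criterion with a
    minimum-resolvable-distance search, closed-form infinite-data beamformer
    images as an analytic oracle, and a volumetric post-movement beta
    rebound mapping pipeline with peak-coordinate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
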