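Package: devatlas
Title: Age-to-Age Translation Machinery for 4D Developmental Brain Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Displacement-field algebra (warping, point mapping, fixed-point
    inversion, composition and temporal scaling), temporally weighted synthesis
    of intermediate-age brain templates and segmentations, translation of
    coordinates and image volumes between arbitrary postnatal ages along a
    chain of pairwise-registered anchor templates, landmark-based
    target-registration-error statistics with rater-concordance comparison,
    template preprocessing operators (downsampling, posterior padding,
    isotropic resampling, origin alignment, 3D CLAHE, mean-intensity
    matching), and distance-weighted K-nearest-neighbour reconstruction of 3D
    expression volumes from sparse registered 2D sections, together with
    region-wise area-fraction quantification. Ships a synthetic-phantom module
    with analytically invertible warp fields so every operation is testable
    without external atlas data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
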