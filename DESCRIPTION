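Package: specfuse
Title: Spectral-Spatial Fusion Classification of Hyperspectral Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying the growth year of plant
    samples (e.g. ginseng roots) from laboratory push-broom hyperspectral
    image cubes. Covers ENVI-style cube input/output, scene segmentation into
    sample and white-reference regions, column-wise white-reference
    radiometric calibration from digital numbers to reflectance, mean
    reflectance curve extraction, random-forest band-importance ranking and
    selection, and a dual-branch fully-connected/convolutional fusion
    classifier (FC-CNN) trained with a mean-absolute-error loss. Includes a
    seeded synthetic scene generator emulating the illumination gradient,
    whiteboard flare, and year-dependent reflectance structure of real
    acquisitions, so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
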