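Package: leafskel
Title: Training-Free Leaf Skeletonization and Phenotype Extraction for
    Leafy Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts one midrib polyline per leaf from RGB images of
    single potted leafy plants without any model training or annotation.
    Leaf regions are isolated by HSV hue thresholding and morphological
    filtering, interior seed points are drawn by stratified grid sampling
    after boundary erosion, and the points are connected greedily into
    skeletons: an angle-difference tracer for plants with random
    (top-view) leaf morphology and a convexity-constrained
    curvature-minimization tracer for regular (front-view) morphology.
    From the skeletons the package computes five geometric phenotypes
    (leaf count, relative crown width, leaf length consistency, leaf
    distribution consistency, leaf height consistency) together with
    curvature-error and leaf-recall evaluation metrics, and ships a
    synthetic plant image generator with exact ground-truth midribs so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
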