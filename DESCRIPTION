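Package: sbwrisk
Title: Landscape-Configuration Risk Modelling for Spruce Budworm Defoliation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially-explicit estimation of eastern spruce budworm
    (Choristoneura fumiferana) infestation likelihood from landscape
    configuration. Provides a seeded neutral-landscape generator for
    multi-year reflectance, land-cover and defoliation-severity rasters;
    multiresolution region-merging segmentation of forest stands;
    class- and landscape-level configuration metrics (mean patch area,
    largest patch index, cohesion, landscape shape index, patch-area
    coefficient of variation, mean shape index) on a 400 m tessellation
    with an 8-neighbour patch rule; rule-based disturbed/undisturbed tile
    labelling; and random-forest likelihood models with temporal and
    stratified cross-validation, ROC threshold selection, permutation
    feature importance and partial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
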