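Package: hippomorph
Title: Contour-Based Hippocampal Volumetry and Radial-Distance Shape
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Subcortical shape morphometry from manually traced contour
    stacks: planimetric volume estimation, parametric surface modelling
    with medial-curve radial-distance maps, total-intracranial-volume
    covariance adjustment of regional volumes, vertex-wise general linear
    models with permutation-based maximum-cluster-size family-wise error
    correction, threshold-free cluster enhancement (TFCE), head/body/tail
    region-of-interest tests, and a synthetic cohort generator with
    known, recoverable localized deformations for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
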