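Package: ParotidOverlap
Title: Overlap-Volume Prediction of Parotid Mean Dose in Helical Radiotherapy Plans
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxel-grid tools and cohort statistics for predicting whether a
    parotid gland's mean dose will exceed the 26 Gy sparing tolerance in
    helical-delivery head-and-neck plans, from fractional overlap volumes
    between the parotid and the planning target volumes (PTVs) and their
    millimetre expansions. Implements contour rasterization, millimetre-true
    isotropic expansion via a Euclidean distance transform, mean-dose and
    coverage statistics, linear regression with backward stepwise AIC
    selection, ROC/Youden threshold calibration, the scenario-stratified
    decision rule (high/intermediate/low dose-level overlap), and a synthetic
    plan-cohort generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, MASS, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
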