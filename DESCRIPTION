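Package: remodelr
Title: Longitudinal HR-pQCT Bone Remodeling and Mechanoregulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extended analysis of time-lapse high-resolution peripheral
    quantitative computed tomography (HR-pQCT) bone images: rigid
    registration of baseline and follow-up density images, voxel-wise
    classification of bone formation, resorption and quiescence across a
    mineral-density threshold ladder, voxel-based micro-finite-element
    compression analysis (strain energy density, effective strain, apparent
    stiffness), and mechanoregulation statistics linking surface remodeling
    events to their local mechanical environment (conditional probability
    curves, remodeling thresholds, correct classification rate). Includes a
    synthetic phantom generator with known ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    ggplot2,
    rlang,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
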