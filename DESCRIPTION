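Package: ldctbmd
Title: Automated Vertebral Bone Mineral Density Measurement from Low-Dose Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated opportunistic-osteoporosis-screening pipeline for
    low-dose chest CT volumes. Segments vertebral bodies with a 3D
    dense-connected U-net, assigns anatomical names (T1-T12, L1, L2) by
    connected-component analysis, places a 9-mm cylindrical elliptical
    trabecular volume of interest in each target vertebra (T12, L1, L2), maps
    mean CT number to volumetric bone mineral density by a first-degree linear
    calibration, and classifies bone mass as normal, osteopenia or
    osteoporosis. Includes a synthetic CT phantom generator with voxel-level
    ground truth so every stage is testable without clinical data, and the
    method-comparison statistics (Dice, labeling accuracy, linear agreement,
    Bland-Altman limits of agreement, ROC/AUC, diagnostic 2x2 tables) used to
    evaluate such systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
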