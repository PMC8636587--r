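Package: limbtorsion
Title: Automatic Measurement of Femoral and Tibial Torsion from Axial MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic pipeline for quantifying lower-limb torsional
    alignment from axial magnetic resonance imaging stacks of the hips, knees,
    and ankles. A three-dimensional U-net segments femur, tibia, and fibula;
    deterministic geometry then locates the femoral head centre, the femoral
    neck axis, the posterior condylar lines, and the distal tibio-fibular
    centroid line, and reports signed femoral and tibial torsion in degrees.
    Includes a parametric lower-limb bone phantom generator with analytically
    known torsion for training and validation, k-space and bias-field
    artifact augmentation, and inter-reader agreement statistics
    (Sorensen-Dice, Pearson correlation, single-score intraclass correlation,
    mean absolute differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    generics,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
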