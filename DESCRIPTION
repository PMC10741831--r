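Package: rmsim
Title: Respiratory Motion Simulation from Single-Phase Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a full respiratory cycle from a single end-of-inhale
    chest projection image. A convolutional encoder compresses the input
    radiograph to a latent vector, a two-layer one-to-many LSTM rolls the
    latent forward through nine respiratory phases, and a decoder with skip
    connections emits per-phase deformation vector fields that a
    differentiable bilinear spatial transformer applies to the input image.
    Includes a seeded synthetic 4D thoracic phantom generator with
    ground-truth displacement fields, a preprocessing path from CT-like
    volumes (threshold lung segmentation, beam's-eye-view ray-cast
    digitally reconstructed radiographs, bounding-box cropping), training
    with smoothness, mean-squared-error and local normalized
    cross-correlation losses, and an evaluation suite producing
    Jacobian-determinant ventilation maps, per-phase Dice scores and
    diaphragmatic position errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
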