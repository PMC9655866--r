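Package: fusedose
Title: Full-Scale Feature-Fusion 3D Conditional-Adversarial Dose Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise prediction of radiotherapy dose distributions with a
    three-dimensional conditional generative adversarial network. Provides CT,
    structure-mask and dose preprocessing (HU truncation, structure labelling,
    isotropic resampling, centred cropping, affine normalization), a full-scale
    feature-fusion encoder-decoder generator and a 3D patch discriminator with
    hand-rolled reverse-mode differentiation, the composite adversarial +
    adjacent-voxel-difference + L1 objective, the alternating training
    protocol, a seeded pelvic phantom generator with analytic reference dose
    fields, and a complete dosimetric evaluation suite (MAE, DVH and dose
    indices, homogeneity and conformity indices, isodose Dice coefficients,
    3D gamma analysis, difference histograms, paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
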