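Package: thinseg
Title: Thickness-Agnostic Semi-Supervised Brain-Ventricle Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-supervised segmentation of brain ventricles across CT and
    MR volumes acquired at different slice thicknesses. Trains an
    encoder-decoder network with sub-pixel convolution upsampling on labeled
    thick-slice images (spacing > 3 mm) together with unlabeled thin-slice
    images, coupling supervised cross-entropy with a Pearson chi-square
    divergence-to-uniform objective on the unlabeled domain. Includes a
    synthetic head-phantom cohort generator with a partial-volume
    thick-slice model, NIfTI I/O, slice-wise inference, Dice evaluation with
    grouped reporting, and a three-experiment ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
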