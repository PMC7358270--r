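Package: cortseg
Title: Cortical and White-Matter Lesion Segmentation with a Valid-Padding 3D U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous segmentation of cortical and white-matter multiple
    sclerosis lesions from co-registered FLAIR and MP2RAGE volumes with a
    three-level valid-padding 3D U-Net. Provides the declarative architecture
    with shape tracing, receptive-field and parameter accounting; the training
    recipe (lesion-balanced patch sampling, class-weighted cross-entropy, L2
    regularisation, warm-up/halving learning-rate schedule, on-the-fly
    augmentation, early stopping); tiled whole-volume inference with
    validation-driven threshold selection; a lesion-wise evaluation suite
    (Dice, volume difference, positive predictive value, lesion-wise detection
    and false-positive rates, size-stratified detection, volume correlation,
    paired statistics); a seeded multi-contrast phantom generator; and
    cross-validation / cross-site experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
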