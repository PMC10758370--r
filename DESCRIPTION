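Package: echonet
Title: Automatic CNN Architecture Design for Ultrasound Lesion
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Searches for compact convolutional network architectures for
    benign/malignant lesion classification in grayscale ultrasound images.
    Provides a three-block backbone family with a square-root kernel-count
    rule, Bayesian optimisation of architectural and training
    hyperparameters with a Gaussian-process surrogate and expected
    improvement, boundary-annotation-driven region-of-interest extraction,
    mirroring and SVD-compression data augmentation, stratified
    cross-validated evaluation with sensitivity/specificity accounting and
    generalization-gap reporting, and saliency-map explainability
    (Grad-CAM, entropy-gated EGrad-CAM, Ablation-CAM) with a zero-entropy
    feature-map audit.  A seeded synthetic speckle-image generator makes
    the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
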