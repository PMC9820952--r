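Package: masseg
Title: Deep-Supervised 3D Residual U-Block Segmentation of Bilateral
    Muscle Structures in CBCT and CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for automatic volumetric segmentation of the
    masseter muscle (and similar bilateral soft-tissue structures) from
    cone-beam CT and conventional CT. Implements a four-stage 3D
    encoder-decoder built from residual U-blocks with deep supervision,
    trained with an equally weighted soft-Dice plus cross-entropy loss under
    momentum SGD with linear warm-up and cosine decay; nnU-Net style
    intensity clipping and z-score normalisation; sliding-window inference;
    Dice and average-Hausdorff evaluation with the class-mean and side-mean
    aggregation conventions used in the masseter literature; Bland-Altman
    and paired-t agreement statistics; and a seeded synthetic CBCT/CT
    phantom generator so the whole pipeline is testable without clinical
    data. All tensor arithmetic is implemented in compiled code behind a
    small reverse-mode differentiation layer; no external deep-learning
    runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
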