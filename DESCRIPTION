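Package: wgseg
Title: Adversarial U-Net Segmentation of Chest Radiographs with a
    Wasserstein Critic
Version: 0.1.0
Authors@R:
    person("wgseg", "developers", email = "wgseg@example.org",
           role = c("aut", "cre"))
Description: Multi-organ (lung fields and heart) semantic segmentation of
    chest-radiograph-like images with an adversarially trained U-Net. The
    generator is a four-level encoder-decoder with squeeze-and-excitation
    channel attention and residual shortcuts; it is trained against a
    convolutional critic under a Wasserstein objective with gradient
    penalty, plus a supervised Dice and cross-entropy term. Includes a
    synthetic thorax phantom generator with exact ground truth, CLAHE
    contrast enhancement, geometric augmentation, color-coded PNG mask
    I/O, overlap metrics (Dice, IoU, recall, precision, F1), and a
    command-line interface, all sized to run on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
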