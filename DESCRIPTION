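Package: lcaugment
Title: Low-Cost Augmentation Policy Search for Imbalanced Medical Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Searches a compact data-augmentation policy space for
    class-imbalanced medical image classification. The space pairs twelve
    color operations with six geometric operations into twelve subpolicies
    governed by a single execution probability, which is selected by
    grouped 5-fold cross-validation on balanced multiclass accuracy and
    then matched to a network on the full training set. Includes an
    inverse-class-frequency weighted cross-entropy loss, multi-crop
    test-time evaluation, Grad-CAM++ class activation heatmaps, a seeded
    synthetic dermoscopy-like image generator for desk-scale experiments,
    a small reference convolutional network backbone, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
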