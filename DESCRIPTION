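Package: frugalseg
Title: Multi-Class Semantic Segmentation on Heterogeneously Labeled Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for training multi-class semantic segmentation models on
    partially (heterogeneously) labeled image datasets, where different
    samples carry ground-truth masks for different subsets of the classes.
    Implements a combined objective that couples a mask-weighted soft Dice
    loss with a class-asymmetric loss exploiting the mutual exclusivity of
    segmentation classes, the Performance Frugality Ratio metric, an online
    heterogeneous-label generator with a per-iteration sample memory, a
    compact encoder-decoder segmentation network trained with Adam, a
    synthetic shape-image benchmark generator, and a four-experiment harness
    for label-ablation, class-transfer, dataset-merging and loss-weighting
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
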