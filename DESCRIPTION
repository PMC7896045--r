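Package: wsiweak
Title: Weakly Supervised Whole-Slide Image Classification at Desk Scale
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Toolkit for slide-level weakly supervised classification of
    whole-slide histopathology images, exercised on synthetic slide corpora.
    Provides a synthetic-slide generator with planted lesions and stratified
    splits; tiling, background filtering and augmentation; a compact
    convolutional backbone with global max- and average-pooling heads,
    receptive-field arithmetic and an Adam training loop; multiple-instance
    learning baselines (top-k selection, EM-based selection, class-histogram
    aggregation, max-feature random forests, recurrent aggregation);
    whole-image training with class-activation-map lesion localization; a
    memory-grouping and prefetch scheduler for compute graphs with a swap
    simulator; and AUC statistics with DeLong confidence intervals, paired
    DeLong tests and bootstrap summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    nnet,
    e1071,
    randomForest,
    png,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
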