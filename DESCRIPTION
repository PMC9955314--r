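Package: tab2img
Title: Importance-Ordered Tabular-to-Image Conversion and Hybrid CNN-SVM
    Classification for Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts numeric clinical feature tables into grayscale images in
    which each feature owns a rectangular cell sized by its ReliefF importance,
    then classifies the images with fine-tuned residual convolutional networks
    and with kernel support vector machines fed by fused deep features.
    Provides ReliefF feature weighting, min-max normalization, a deterministic
    guillotine cell layout on a 120x120 canvas, affine image augmentation
    (reflection, rotation, scaling, translation), compact residual networks of
    depth 18 and 50 with stochastic-gradient-descent fine-tuning and
    penultimate-feature extraction, deep-feature fusion with ReliefF
    re-selection, and the six confusion-matrix metrics (accuracy, specificity,
    precision, sensitivity, F1, Matthews correlation coefficient). A
    class-conditional Gaussian simulator generates benchmark-shaped tables so
    the whole pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    EBImage,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
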