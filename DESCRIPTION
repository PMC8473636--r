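Package: scaraug
Title: GAN Augmentation and Attention Classifiers for Myocardial Scar MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying generative-adversarial-network (GAN) data
    augmentation in binary classification of late-gadolinium-enhancement
    (LGE) cardiac MR images. Provides a synthetic short-axis cardiac phantom
    generator with ground-truth scar masks, balanced traditional augmentation
    (rotation pools with flip/shift/scale), a progressive-growing GAN and a
    CycleGAN built on a small self-contained convolutional engine, PCA plus
    k-means one-sigma filtering of generated images, Frechet inception
    distance scoring, a MobileNetV2-style depthwise-separable classifier with
    pluggable channel/spatial/mix attention units, and Grad-CAM heatmaps with
    region-of-interest and scar-localization metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
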