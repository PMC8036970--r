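Package: tmeseg
Title: Semi-Supervised Adversarial Segmentation and Quantification of
    Tumor-Microenvironment Biomarkers in Histology Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-pixel cellular-biomarker class maps (background,
    PanCK-positive tumor, CD3/CD20-positive tumor-infiltrating lymphocytes,
    DAPI nuclei) from H&E-like RGB image patches with a semi-supervised
    adversarial strategy: an encoder-decoder segmentation generator is trained
    jointly with a fully convolutional discriminator whose per-pixel confidence
    map gates self-training on unlabeled patches. Includes a seeded synthetic
    tissue-scene simulator, the patch preparation pipeline (tiling, Reinhard
    color normalization, background and tumor-fraction filters, mask-safe
    augmentation), the adversarial and semi-supervised loss functions, a
    multilabel mutation classifier for APC/TP53/KRAS status, macro-averaged
    segmentation metrics with ROC/AUC, and downstream quantification of class
    fractions and PD-1-expressing lymphocytes. The small convolutional-network
    engine (convolution, pooling, batch normalization, bilinear resampling,
    backpropagation, Adam/RMSprop) is implemented in C++ via RcppArmadillo so
    the scaled-down presets train on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
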