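Package: cxrgrade
Title: Ordinal Grading of Lung Opacity on Chest Radiographs by Staged
    Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A multi-level pipeline for estimating per-lung opacity burden
    on chest radiographs as a four-class ordinal label (clear, 1-33%,
    34-66%, 67-100% lung involvement). Provides a synthetic phantom
    radiograph generator with known per-lung coverage fractions and
    acquisition artifacts; cohort exclusion and de-duplication rules;
    three region-of-interest schemes (whole image, per-lung masking via an
    encoder-decoder segmenter, spine-based lateral splitting); leakage-free
    patient-level cross-validation splits with three class-balancing
    strategies; two-stage fine-tuning of convolutional classifiers on a
    compact compiled conv-net backend; ordinal evaluation metrics
    (macro-averaged MAE, weighted precision/recall/F1, R-squared, binary
    collapses); Grad-CAM saliency with a probability-weighted attention
    heatmap and the Heatmap Concordance Score (HCS) against lung masks; and
    the three-stage model-selection procedure combining macro-MAE with
    macro-averaged HCS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
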