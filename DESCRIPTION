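Package: nutriface
Title: Facial-Feature Pipeline for NRS-2002 Nutritional Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline that screens for nutritional risk
    (NRS-2002 score >= 3) from face photographs. Implements landmark-based
    face alignment and cropping, orbital-fat-pad segmentation with a
    convolutional encoder-decoder (U-net) trained by RMSProp on binary
    cross-entropy, ROI-restricted histogram-of-oriented-gradients texture
    features with z-score standardization and PCA reduction, RBF-kernel
    support-vector-machine classification, and 2x2 chi-square subgroup
    statistics. Ships a synthetic-face cohort generator so every stage is
    exercisable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
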