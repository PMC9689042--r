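Package: liverQUS
Title: Quantitative Ultrasound Texture Analysis for Liver Fibrosis Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for staging liver fibrosis from B-mode ultrasound texture.
    Provides a calibrated two-class speckle-image simulator for early and
    advanced fibrotic liver parenchyma, extraction of sixteen first-order,
    gray-level run-length and gray-level co-occurrence (Haralick) texture
    features from regions of interest, Welch t-test feature screening,
    reference implementations of logistic regression, Gaussian naive Bayes
    and a single-hidden-layer perceptron producing probabilities of advanced
    fibrosis, and ROC/AUC evaluation under leave-one-out, k-fold and
    percentage train-test sampling schemes with coefficient-of-variation
    summaries of AUC stability.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    jsonlite,
    png,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
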