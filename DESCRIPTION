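Package: weednov
Title: One-Class Novelty Detection for Weed Mapping in Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a target weed in high-resolution multispectral
    (green/red/NIR) imagery using one-class (novelty detection) classifiers
    trained on target-class pixels only. Implements four detectors sharing a
    score-then-threshold contract: Support Vector Data Description (one-class
    SVM), a one-class self-organizing map thresholded on quantization error,
    a single-hidden-layer autoencoder thresholded on reconstruction error,
    and principal-component subspace reconstruction distance. Includes a
    synthetic multispectral scene simulator with labelled weed patches,
    local-variance texture features, balanced calibration sampling with a
    stratified train/test split, confusion-table accuracy assessment
    (overall, user's, producer's, omission and commission errors), and an
    end-to-end pipeline with multi-band TIFF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    EBImage,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
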