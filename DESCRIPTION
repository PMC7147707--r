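Package: thermofoot
Title: Plantar Thermogram Segmentation and Thermal Change Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for infrared plantar thermograms of diabetic
    and control subjects. Provides fuzzy-entropy multilevel histogram
    thresholding optimized with Differential Evolution to isolate the
    hottest plantar region, angiosome-based thermal change index (TCI)
    computation and five-level grading against a control reference,
    region-of-interest feature extraction, patch extraction with
    rotation/flip augmentation, a compact convolutional network (DFTNet)
    for patch classification implemented natively, classical MLP and SVM
    baselines under a one-vs-one pairing scheme, and the standard
    six-metric evaluation (sensitivity, specificity, precision, accuracy,
    F-measure, AUC). A synthetic thermogram generator with controlled
    thermal structure supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff,
    nnet,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
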