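Package: physiofear
Title: Fear Recognition from Electrodermal and Heart-Rate-Variability Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for binary fear recognition from peripheral
    physiological signals: simulation of recording sessions in the DEAP style
    (512 Hz skin conductance, photoplethysmogram and status-marker channels
    with known ground truth), FIR low-pass filtering and decimation to 16
    samples/s, status-driven trial segmentation, decomposition of skin
    conductance into tonic (SCL) and phasic (SCR) components with discrete
    response detection, extraction of 40 named time-, frequency- and
    event-related features per analysis window under non-overlapping and
    overlapping windowing schemes, two-stage class balancing (random majority
    undersampling followed by SMOTE minority oversampling), and grid-searched,
    cross-validated classification (SVM, k-nearest neighbours, random forest,
    gradient-boosted trees) with a repeated stratified split protocol and a
    full metric suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    ranger,
    xgboost,
    glmnet,
    pROC,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
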