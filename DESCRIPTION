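Package: msbgwo
Title: Master-Slave Binary Grey Wolf Optimizer for Wrapper Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper feature selection for high-dimensional two-class
    biomedical data using the master-slave binary grey wolf optimizer
    (MSBGWO) and the BGWO2 baseline. Candidate feature subsets are encoded
    as binary wolf positions, updated by leader-guided grey-wolf moves with
    sigmoid-transfer binarization, and scored by the 10-fold cross-validated
    accuracy of a k-nearest-neighbour classifier combined with a subset-size
    penalty. Includes a synthetic high-dimensional two-class data generator
    with planted informative features, a multi-run experiment driver with
    Wilcoxon rank-sum comparison between optimizers, and the full
    confusion-matrix metric suite (accuracy, precision, recall, F-measure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
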