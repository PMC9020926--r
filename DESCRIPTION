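Package: dnabindR
Title: Sequence-Based Identification of DNA-Binding Proteins via
    Position-Relative Incidence Matrices and Statistical Moments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms raw protein sequences into a 120-dimensional
    composition- and position-based feature vector (amino-acid frequency
    vector, accumulative absolute position incidence vectors for the
    forward and reversed sequence, and raw, central and discrete Hahn
    moments of the 20x20 position-relative incidence matrices), and
    trains and evaluates binary DNA-binding/non-binding classifiers
    (random forest, support vector machine, and a single-hidden-layer
    neural network with an adaptive learning rate) under four validation
    protocols: k-fold cross-validation, jackknife, self-consistency and
    an independent train/test split. Reports sensitivity, specificity,
    accuracy and the Matthews correlation coefficient in two equivalent
    formulations, together with ROC curves. Includes a seeded synthetic
    sequence generator so the whole pipeline is testable without any
    external benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
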