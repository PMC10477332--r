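Package: miqfs
Title: Hybrid MIC-QPSO Feature Selection for EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage hybrid feature selection for multichannel EEG
    classification. Per-channel signals are decomposed into the five
    clinical frequency bands by a six-level discrete wavelet transform and
    summarised by five feature families (C0 complexity, approximate
    entropy, Higuchi fractal dimension, Hjorth parameters, mean power
    spectral density). A filter stage ranks features by their maximal
    information coefficient (MIC) with the class label, removing
    irrelevant features and the less-relevant member of each highly
    MIC-correlated pair. A wrapper stage then jointly optimises the
    binary feature mask and the Gaussian-kernel SVM hyperparameters (C,
    sigma) with quantum-behaved particle swarm optimisation (QPSO) under
    a dimension-aware fitness that trades classification accuracy
    against dimensionality reduction. Includes synthetic generators for
    planted-structure feature tables and two-class multichannel EEG
    epoch sets, a leak-free outer cross-validation pipeline, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
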