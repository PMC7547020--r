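Package: gaclassify
Title: Genetic-Algorithm Optimization of Transfer-Learning Classifiers
    for Small Radiographic Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for optimizing shallow image classifiers built on
    pretrained-network feature embeddings when only small radiographic
    datasets (hundreds of images) are available. Provides a declarative
    ten-axis categorical hyperparameter search space, a simple genetic
    algorithm with AUC fitness, a single fully-connected classification
    head with a catalogue of first-order optimizers, a stochastic image
    augmentation pipeline (grid distortion, rotation, zoom, flips),
    region-of-interest obfuscation for signal-localization experiments,
    patient-level cross-validation with leakage-aware fold designs, and
    a patient-structured synthetic phantom image generator for
    end-to-end testing without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
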