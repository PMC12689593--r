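Package: quanvolve
Title: Hybrid Quantum-Classical Convolutional Networks with Knowledge
    Distillation for Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid quantum-classical image-classification
    pipeline: a dense statevector simulator for small qubit registers (RY
    and CNOT gates, parameterized entangling layers, Pauli-Z expectations,
    parameter-shift gradients), a quanvolution operator that encodes 2x2
    image patches into a 2-qubit circuit and assembles quantum feature
    maps, small convolutional classifiers trained by backpropagation, and
    a teacher-student knowledge-distillation objective combining
    cross-entropy with temperature-softened Kullback-Leibler divergence.
    Includes a seeded generator of class-imbalanced grayscale phantom
    images for end-to-end benchmarking, repeated stratified hold-out
    evaluation with per-class precision/recall/F1 and one-vs-rest AUC,
    and a config-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC,
    optparse
Config/testthat/edition: 3
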