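Package: phenocnn
Title: Convolutional Patient Phenotyping from Clinical Notes with Token Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts patient phenotypes from free-text clinical notes with
    word-level and combined word- plus sentence-level convolutional neural
    networks (w-CNN, ws-CNN). Provides the full experimental stack: note
    cleansing, tokenization, sentence segmentation, indexing and padding;
    CBOW word embeddings with an index-aligned lookup table; max-over-time
    pooled convolutional classifiers trained with class-weighted
    cross-entropy, Adadelta and max-norm regularization; stratified k-fold
    cross-validation, learning curves, Zipf rank-frequency analysis, token
    frequency filtering and greedy token-category prioritization. A synthetic
    note generator with Zipf-distributed background vocabulary and
    category-tagged signal tokens makes every stage testable without access
    to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
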