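Package: deidtag
Title: De-Identification of Clinical Notes with a Feature-Augmented
    BiLSTM-CRF Tagger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tags Protected Health Information (PHI) in clinical notes with a
    character- and word-level bidirectional LSTM sequence model topped by a
    linear-chain conditional random field. Includes text pre-processing with
    character-offset provenance (run-together-word repair, sentence splitting,
    tokenization, BIO conversion), lexical (part-of-speech, word-shape) and
    knowledge-based (fuzzy gazetteer lookup) feature streams fed through a
    feature-embedding layer, pretrained word-vector loading with UNKNOWN
    fallback, strict and relaxed span-matching evaluation with a four-way
    error taxonomy, two cross-institute customization strategies (corpus
    merging and fine-tuning), and a seeded generator of surrogate-PHI
    clinical notes in two institution styles so the full pipeline runs
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
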