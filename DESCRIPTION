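Package: termlink
Title: Cross-Lingual Medical Terminology Normalization by String and
    Semantic Score Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Ranks reference-dictionary concepts (for example UMLS
    disorder concepts) for free-text medical terms by combining
    character n-gram TF-IDF string similarity with dense semantic
    similarity. Provides readers for MRCONSO-style pipe-delimited and
    TSV concept dictionaries, a multi-provider translation-variant
    unification step with a deterministic table-driven mock provider,
    score-fusion schemes (z-score, min-max, tanh, and a trainable
    linear combination optimized by a marginal-probability loss over
    mined top-k candidate pools), a top-n accuracy and McNemar paired
    significance evaluation harness, and a seed-reproducible synthetic
    benchmark generator with controllable string and semantic channel
    informativeness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
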