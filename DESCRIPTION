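Package: reviewminer
Title: Topic Mining and Patient-Interest Analysis for Physician Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for mining patient-experience topics from physician review
    corpora. Implements collapsed-Gibbs latent Dirichlet allocation (LDA) and
    labeled-LDA for multi-label topic classification against a nine-topic
    patient-experience taxonomy, per-word perplexity with topic-number
    selection, multi-label precision/recall/F evaluation, and group-wise
    patient-interest comparison (thresholded topic ratios, containment
    fractions, Welch t tests, Cohen's d with published effect-size bands).
    Includes a labeled-LDA synthetic corpus generator with group-dependent
    topic prevalences and a text-preprocessing pipeline (pluggable tokenizer,
    part-of-speech filtering, stopword removal, synonym canonicalization, and
    rule-based entity placeholder substitution).
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
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
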