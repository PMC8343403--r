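Package: pkTriage
Title: Triage of Pharmacokinetic Literature by Gradient-Boosted Document Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies scientific publications that report newly estimated
    in-vivo pharmacokinetic (PK) parameters from PubMed/MEDLINE records.
    Provides MEDLINE XML parsing into typed document corpora, the
    token-normalisation chain used for PK literature triage (rule-based
    tokenisation, chemical-mention masking, digit masking, stopword removal,
    Porter stemming), field-selected n-gram bag-of-words encoding with
    per-document L1 normalisation, pluggable token- and document-level
    embedding providers with mean and min/max pooling, a class-weighted
    gradient-boosted tree classifier with F1-based early stopping, and the
    evaluation machinery to compare pipelines: stratified bootstrap
    resampling with median/CI/IQV summaries, Cohen's kappa inter-annotator
    agreement, and exhaustive grid-search cross-validation. A synthetic
    corpus generator emulates the statistical structure of labelled PK
    corpora so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    xgboost,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
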