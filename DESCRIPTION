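Package: promnlp
Title: Rule-Based Detection of Patient-Reported Outcome Measure
    Documentation in Clinic Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding documented use of patient-reported outcome
    measures (PROMs) in free-text clinic notes. Provides corpus preparation
    (per-visit note concatenation, metadata headers, exclusive visit
    categories, token-length statistics, stratified annotation sampling), a
    configurable PROM lexicon with alias, abbreviation and fuzzy matching, a
    section-aware rule-based span matcher with include/exclude section
    filtering, span- and note-level evaluation (strict-boundary,
    soft-boundary and note-categorization tasks, inter-annotator agreement,
    AUC-ROC), Monte Carlo and repeated k-fold cross-validation with 95%
    confidence intervals, compact bag-of-words, convolutional and ensemble
    note classifiers, and a synthetic sectioned-note generator with gold
    standard span annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
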