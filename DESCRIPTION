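Package: lingdx
Title: Linguistic Biomarker Screening and Diagnostic Modelling for Dementia Speech
Version: 0.1.0
Authors@R: person("lingdx", "maintainers", email = "lingdx@example.org", role = c("aut", "cre"))
Description: Extracts syntactic, lexical and word n-gram features from
    CHAT-formatted speech transcripts (CHILDES/TalkBank dialect), screens
    them with pooled two-sample t-tests, Mann-Whitney U tests and
    age-adjusted multiple logistic regression, ranks features by
    information gain, and evaluates RBF-kernel support vector machine
    diagnostic models with leave-pair-out cross-validated AUC and its
    closed-form variance. Includes a synthetic two-group cohort generator
    that emulates picture-description speech so the whole pipeline can be
    exercised without access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
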