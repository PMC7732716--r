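Package: adescreen
Title: Screening Medical Articles for Adverse Drug Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage screening system for pharmacovigilance literature
    monitoring under recall-based reporting. Classifies medical articles as
    ADE-containing (document level) and flags ADE-suggesting sentences within
    them (sentence level) using character-level named entity recognition of
    disease and drug names, edit-distance dictionary normalization,
    interpretable sparse bag-of-words and entity feature groups, and L2
    regularized logistic regression. Includes a stratified cross-validation
    evaluation harness with precision-recall curves, feature-group ablation,
    learning curves and Cohen's kappa, plus a seeded synthetic corpus
    generator that emulates the statistical structure of annotated Japanese
    case-report corpora so the whole pipeline is testable without private
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
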