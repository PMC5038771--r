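Package: roughpd
Title: Rough-Set Analysis of Reflexive-Saccade and Clinical Attributes in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rough-set machinery for predicting Unified Parkinson's Disease
    Rating Scale (UPDRS) scores and treatment session (medication x deep-brain
    stimulation state) from reflexive-saccade measurements and clinical scales.
    Provides typed information/decision tables, supervised
    (maximal-discernibility) and equal-frequency discretization with
    star-elimination of non-significant attributes, indiscernibility granules,
    lower/upper approximations, reducts, decision-rule induction with
    support/confidence voting, template-based decomposition-tree classifiers,
    fold-averaged cross-validation with coverage-aware accuracy, Matthews
    correlation and Cohen's kappa, SMOTE-style oversampling, native baseline
    classifiers, and a seeded synthetic-cohort generator for repeated-measures
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
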