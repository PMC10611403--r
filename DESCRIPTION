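Package: mmjive
Title: Multilevel Joint and Individual Variation Analysis for Two-Domain
    Wearable Feature Panels
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the information shared between two blocks of
    daily wearable-derived features measured repeatedly on the same
    subjects, such as gait features from a lumbar accelerometer and
    physical-activity features from a wrist accelerometer. Provides a
    validated long-format panel data model with valid-day filtering and
    scaling; a synthetic-data generator with planted joint and individual
    low-rank structure at the between- and within-subject levels; one-level
    analyses (pairwise Pearson correlation, Lasso regression with five-fold
    cross-validation and the one-standard-error rule, principal component
    regression); domain-level analyses (two-block partial least squares and
    joint-and-individual-variation-explained (JIVE) decomposition with
    permutation rank selection); multilevel extensions (ANOVA-style
    between/within decomposition, multilevel PCA, multilevel PLS and
    two-step multilevel JIVE); and a single orchestrating entry point that
    writes deterministic machine-readable report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
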