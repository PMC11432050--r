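Package: iseScreen
Title: Iterative Stochastic Elimination Models for Ligand-Based Virtual
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains filter-ensemble classifiers by Iterative Stochastic
    Elimination (ISE) from imbalanced actives-versus-decoys molecular
    descriptor tables, screens compound libraries with signed weighted
    filter scores in [-1, 1], and derives drug-target activity and
    interaction matrices, per-cutoff prediction reports, repurposing
    candidate lists with anti-target exclusion, and ECFP4 Tanimoto
    diversity statistics. Includes applicability-domain decoy selection,
    stratified cross-validation with MCC/AUC/TPR/TNR/F metrics, and a
    synthetic planted-signal generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
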