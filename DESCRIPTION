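Package: embryoscreen
Title: Block-Stratified Biomarker Screening for Spent Embryo Culture-Medium
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of untargeted LC-MS feature tables from single
    embryo culture medium (replicate averaging, consistency filtering,
    random-forest imputation, total-intensity normalization, blank
    subtraction), exhaustive fixed-factor block screening of pregnancy
    endpoints with a two-level volcano plus ROC-AUC gate, stage-abundance
    ("impact") weighting of single-biomarker coverage, and series-wise
    combination of stage-disjoint blocks into combined coverage. Includes a
    synthetic-cohort generator with planted effects so the whole pipeline is
    testable end to end, plus whole-dataset endpoint models, taxonomy and
    endpoint tallies, and descriptive pregnancy-rate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    withr,
    yaml
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
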