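Package: pdxsite
Title: Tissue-of-Origin Classification for PDX Expression Profiles via
    Monte Carlo Feature Selection, Incremental Feature Selection and
    Threshold Rules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a complete pipeline for testing whether
    primary-tumor-site identity is preserved in patient-derived xenograft
    (PDX) expression profiles: Monte Carlo feature selection (MCFS) with a
    permutation-derived informative-feature threshold, two-stage incremental
    feature selection (IFS) around a one-vs-rest support vector machine with
    stratified cross-validation and multi-class performance metrics
    (including the Gorodkin multi-class Matthews correlation coefficient),
    and induction, application and evaluation of ordered IF-THEN expression
    threshold rules (MDL discretization, Johnson reducer, RIPPER-style
    sequential covering). Ships the published 16-rule tissue classifier as a
    loadable fixture and a synthetic-data generator emulating the 8-tissue
    PDX cohort with planted marker genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, GeneExpression
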