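Package: xenorules
Title: Feature Ranking and Interpretable Rule Learning for Xenograft
    Versus Original Tumor Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for identifying genes differentially expressed
    between patient-derived xenograft (PDX) and original human tumor
    cells from single-cell expression matrices. Implements Monte Carlo
    feature selection (relative-importance ranking over random
    projection trees), incremental forward selection with
    cross-validated random-forest evaluation scored by the
    covariance-form Matthews correlation coefficient, and rough-set
    rule learning (generalized decisions, discernibility functions,
    Johnson reduct, RIPPER rule induction with FOIL gain) yielding
    ordered IF-THEN threshold rules and a rule-interaction network.
    Includes a synthetic-data generator with planted informative genes
    and planted threshold rules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
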