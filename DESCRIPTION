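Package: cpgselect
Title: Two-Stage CpG-Site Selection for DNA-Methylation Age Prediction
Version: 0.1.0
Authors@R:
    person("cpgselect", "developers", email = "cpgselect@example.org",
           role = c("aut", "cre"))
Description: Selects age-informative CpG sites from DNA-methylation beta-value
    matrices with a two-stage framework: age-range classification (PCA plus a
    linear classifier, with confusion-matrix-driven merging of decade classes
    into age groups) followed, per age group, by a partition-parallel genetic
    algorithm whose fitness is a cross-validated gradient-boosted-regression
    mean absolute deviation plus a selected-site-count penalty, and a stepwise
    forward ranking of the winning CpG panel. Includes readers for delimited
    beta matrices and GEO series-matrix files, a preprocessing chain
    (null removal, mean imputation, min-max normalization, outlier removal,
    train/test splitting), and a synthetic methylation-aging cohort generator
    with planted informative sites for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    glmnet,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
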