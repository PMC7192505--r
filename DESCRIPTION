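Package: tmscan
Title: Systematic Scanning of Translational Drug-Response Modeling Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for systematically scanning the model space of
    translational drug-response pipelines: models trained on cell-line
    screens (gene expression plus ln(IC50) drug response) and evaluated on
    patient cohorts with binary clinical response. Implements the full
    pipeline grid of cell-response transforms, train/test homogenization
    and batch-effect correction (including a principal-component RUV with
    housekeeping-gene negative controls and a cumulative-proportion
    transform), feature filters and preprocessors, and seven regression
    black boxes, together with ROC/PR evaluation, random-response and
    gene-permutation null distributions, drug-specificity ranking,
    hypergeometric setting-enrichment statistics, in-vitro cross-validation
    baselines, and a synthetic-data generator that emulates the
    cell-line-to-patient batch shift so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    sva,
    car,
    glmnet,
    randomForest,
    ranger,
    e1071,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
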