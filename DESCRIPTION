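Package: tripath
Title: Mining Ordered Disease Triplet Pathways from Longitudinal Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis-led mining of ordered disease triplet pathways
    (hierarchical disease triplet clusters) from longitudinal claims
    histories of matched case-control cohorts. Validates incident
    diagnoses from outpatient/inpatient claims, enumerates every ordered
    disease triplet preceding the index date, screens triplets against
    case status by univariable logistic odds ratios, expands retained
    triplets into seven groups of ordinal and nonordinal binary features,
    selects features by one-model or by-group LASSO, classifies with
    linear support vector machines or random forests under 3-fold
    cross-validation, and renders the retained pathways as disease trees
    and a directed temporal disease network. Includes a seeded generator
    of synthetic matched claims cohorts with planted ordered pathways so
    the full pipeline is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    glmnet,
    e1071,
    randomForest,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
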