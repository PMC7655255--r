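Package: survSigSearch
Title: Exhaustive Survival-Signature Search for Prognostic Expression Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and evaluation of small prognostic gene-expression
    signatures in survival cohorts. Provides prevalence filtering and
    univariate Cox screening of a log2-normalized expression matrix,
    exhaustive AUC-maximizing traversal of all one- to three-gene
    multivariate Cox models, risk-score stratification with Kaplan-Meier,
    log-rank, concordance-index and ROC-AUC evaluation, cross-platform
    projection of a signature onto platforms missing some of its genes,
    Pearson coexpression screening, and a repeated-subsampling harness for
    comparing competing signatures. Includes a survival-cohort simulator
    with planted proportional-hazards signatures so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC
Config/testthat/edition: 3
biocViews: Survival, GeneExpression, Regression, Classification
RoxygenNote: 7.3.3
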