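Package: sigleak
Title: Signature Scoring and Leakage-Aware Evaluation of Transcriptomic
    Node-Status Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating gene-expression signatures that claim to
    predict pathologic lymph-node status from bulk tumour transcriptomes.
    Implements directional mean signature scores with data-driven
    directionality inference, moderated-t differential expression with
    Benjamini-Hochberg correction, gene-list overlap tests against analytic
    and simulated chance expectations, pre-ranked gene set enrichment, and
    repeated stratified nested cross-validation of elastic-net and
    random-forest classifiers with internal (leakage-free) versus full-data
    (leaky) feature selection. A synthetic two-cohort generator with planted,
    partially shared signal provides ground truth for auditing selection bias
    and cross-cohort transferability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, Classification, DifferentialExpression,
    GeneSetEnrichment, Software
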