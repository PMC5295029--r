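Package: mirmint
Title: Integrative miRNA-mRNA Expression Analysis for Treatment-Response Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline for paired miRNA and gene
    expression cohorts with a binary treatment-response outcome. Implements
    sparse partial least squares discriminant analysis with cross-validated
    tuning, random-variance moderated t-tests with false discovery rate
    control and a global permutation test, gene-set enrichment analysis
    against continuous component-score traits, regularized canonical
    correlation analysis with correlation-circle and clustered-image-map
    summaries, miRNA-target anticorrelation networks integrated with
    multi-database target-prediction consensus, and network-smoothed
    t-statistic feature selection with repeated cross-validated support
    vector machine classification. Includes a synthetic-cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mixOmics,
    MASS,
    withr
Config/testthat/edition: 3
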