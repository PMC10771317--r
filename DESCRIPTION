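Package: numts
Title: miRNA Target-Site Abundance from Alternative Polyadenylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies per-sample, per-miRNA-family target-site abundance
    (numTS) by combining 3'UTR alternative-polyadenylation state (PDUI),
    target-site annotations partitioned at the proximal polyA boundary, and
    mRNA expression. Provides the downstream biomarker toolkit built on that
    quantity: correlation-disruption tests between numTS and miRNA
    expression, cancer-type separability metrics (between-group variance
    rate, PCA, group Mahalanobis distances), elastic-net predictive models
    with nested cross-validation and bootstrap stability selection,
    hypergeometric replication tests, and Cox survival models augmented with
    tumor-normal numTS changes. A synthetic-cohort generator reproduces the
    statistical structure the analyses assume so the whole pipeline is
    testable without controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
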