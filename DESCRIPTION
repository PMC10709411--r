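Package: omixnet
Title: Integrated Expression-Methylation Gene Networks for Survival Risk
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a single gene network whose edge weights blend absolute
    gene-expression correlation with absolute gene-level DNA-methylation
    correlation through an integrative factor mu, detects gene modules by
    topological-overlap clustering, summarizes each module into expression,
    methylation, and combined eigengenes via risk-balanced PCA, and uses
    lasso-Cox selection with accelerated failure time modeling and
    recall-constrained precision-maximizing cutoffs to stratify patients
    into low-, intermediate-, and high-risk survival groups. Includes a
    seeded synthetic multi-omics cohort generator with planted module and
    survival structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    mclust,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
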