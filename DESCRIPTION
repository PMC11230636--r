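Package: driversub
Title: Driver-Gene-Centred Multi-Omics Subtyping of Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stratifies tumor cohorts into molecular subtypes from driver
    genes and their family members. Protein domains with significant
    mutation burden are found by a seeded permutation test and scored for
    family-wide dispersion with a normalized entropy statistic;
    driver-dysregulated genes are assembled by linking differential
    expression to correlated promoter methylation, miRNA, or copy-number
    evidence; binary mutation profiles are smoothed by network propagation,
    fused with expression via similarity network fusion, and clustered by
    subsampled consensus clustering with silhouette-based model selection.
    Includes subtype characterization (chromosomal instability, mutation
    association, survival separation), an elastic-net plus support-vector
    subtype classifier with a mean-interval marker filter, and a fully
    synthetic multi-omics cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
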