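Package: lumascore
Title: Luminal Progenitor Hierarchies and Breast-Cancer Subtype Signature Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping normal breast luminal single cells
    into a progenitor hierarchy and scoring their differential-expression
    signatures against bulk breast-cancer subtype expression profiles.
    Includes a negative-binomial single-cell count simulator with planted
    marker structure and a planted-signature bulk reference generator, cell
    quality filtering, log normalization and PCA, graph-based clustering with
    donor-mixing entropy diagnostics, one-vs-rest Wilcoxon differential
    expression with Bonferroni correction, expression signature scoring of
    bulk subtype references with Kruskal-Wallis and Dunn post-hoc comparison,
    nearest-centroid subtype association, and minimum-spanning-tree plus
    principal-curve pseudotime inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
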