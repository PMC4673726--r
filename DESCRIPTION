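Package: femnet
Title: Functional Epigenetic Module Discovery from Matched DNA Methylation
    and Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of promoter DNA methylation and gene
    expression on a protein-protein interaction network. Collapses
    Illumina 450k-style probe-level beta values to gene level by promoter
    region priority, computes empirical-Bayes moderated t-statistics for
    both data types, weights interactome edges by an anti-correlation
    gated integrated statistic, and discovers functional epigenetic
    module (FEM) hotspots by seeded greedy search with permutation-based
    significance and independent-cohort validation. Also provides
    per-sample FEM deviation scores against a normal reference,
    binary deviation matrices with a coordination versus mutual
    exclusivity permutation test, nearest-centroid integrative subtype
    classification, interactome shortest-path contrasts against copy
    number, gene-set overlap enrichment, and a synthetic matched-cohort
    generator with planted module structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
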