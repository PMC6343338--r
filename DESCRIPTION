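Package: apacca
Title: Shrinkage Canonical-Correlation Similarity and Clustering for
    Replicated Poly(A) Site Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the association between genes from poly(A)-site
    count data measured across multiple experiments with replicates.
    Each gene is represented by the block of its alternative
    polyadenylation sites; the similarity of two genes is the
    significance-weighted combination of their canonical correlations,
    computed from site-site correlation coefficients that shrink the
    per-experiment replicate variance towards a pooled estimate.  The
    package also provides site filtering and relative-usage
    quantification, hierarchical clustering with silhouette-based
    selection of the number of clusters, internal/stability/biological
    cluster validation indices (connectivity, Dunn, AD, ADM, BHI),
    weighted-network summaries (eigenvector centrality, clustering
    coefficient, modularity), module eigengene and hub-gene extraction,
    and a seeded binomial simulator of replicated poly(A)-site data
    with optional planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    parallel,
    cluster,
    igraph,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
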