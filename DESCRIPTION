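Package: rwhn
Title: Context-Specific Function Inference for Phosphorylation Sites via
    Random Walks on Multilayer Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a three-layer heterogeneous network from clustered
    quantitative phosphoproteomics data (phosphorylation sites, proteins,
    and functional annotation terms) and ranks annotation terms for each
    regulation cluster with a random walk with restart. Includes
    regulation filtering, left-censored imputation, quantile
    normalization and fuzzy C-means / k-means clustering of site
    profiles; construction of the five adjacency blocks (correlated
    same-cluster sites, a STRING-derived protein interaction layer,
    Wang-semantic-similarity or annotation-profile-similarity term
    edges, site-protein and protein-function bipartite edges via Louvain
    modules and hypergeometric enrichment); permutation-based
    significance of term ranks; an over-representation-analysis
    baseline; and a synthetic-study generator with planted
    cluster-to-function ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
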