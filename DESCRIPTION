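Package: seasonet
Title: Seasonal Metabolite Correlation Networks for Seed Physiology
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Correlation-network analysis of seasonal seed metabolome profiles
    and their association with physiological traits (germination and survival
    percentage). Implements the full pipeline: per-metabolite mean
    normalization, arcsine transformation of trait percentages and pareto
    scaling; Shapiro-Wilk normality screening; all-pairs Spearman rank
    correlation with an exact small-sample permutation null and
    Benjamini-Hochberg control of the edge false discovery rate; signed
    correlation-network construction under dual (coefficient, p-value)
    thresholds with the coefficient threshold selected by robustness of four
    network properties across a p-value grid; random-walk (walktrap) community
    detection with a modularity-maximizing dendrogram cut; a Wilcoxon
    signed-rank test of community cohesiveness comparing within-community node
    degrees against residual degrees after intra-community edge deletion; and
    trait-neighborhood subgraph extraction with correlation-sign summaries.
    Ships a synthetic seasonal-metabolome generator with planted block and
    trait-coupling structure so every stage is testable against a known ground
    truth, plus Cytoscape-readable GraphML/SIF export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, Network, GraphAndNetwork, Clustering
RoxygenNote: 7.3.3
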