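Package: netPharm
Title: Multiscale Network Pharmacology from Docking Hits to Clinical Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiscale network-pharmacology analysis of
    multi-ingredient (herbal) drugs. Implements virtual-screening hit
    selection from docking-score tables, construction of layered bipartite
    networks (drug-target, target-pathway, drug-pathway, pathway-disease),
    degree and normalized betweenness statistics with degree stratification,
    stratum-wise pathway relevance-frequency scores, disease category,
    symptom and Cold/Hot ZHENG phenotype summaries, per-disease mechanism
    subnetwork extraction, and rank-based Kolmogorov-Smirnov connectivity
    scoring of expression signatures with permutation p-values. A seeded
    synthetic-data generator with planted structure makes every pipeline
    stage testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'hitFilter.R'
    'networkCore.R'
    'projection.R'
    'phenotype.R'
    'connectivity.R'
    'synthetic.R'
    'pipeline.R'
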