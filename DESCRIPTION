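Package: alloscan
Title: Alanine Sequence Masking and Ensemble Network Analysis of Kinase
    Conformational States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Front-end and back-end tooling for studying conformational
    ensembles of state-switching protein kinases with sequence-masking
    adaptations of structure predictors. The front-end implements randomized
    and region-targeted alanine sequence masking with shallow-MSA prediction
    job planning, emitting FASTA inputs and job manifests for an external
    predictor. The back-end reads multi-model PDB ensembles, filters models
    by per-residue confidence (pLDDT), classifies conformational states by
    RMSD and TM-score against reference ensembles, performs principal
    component analysis of merged ensembles on common reference components,
    computes dynamic cross-correlation and mutual-information generalized
    correlation matrices, and builds correlation-weighted residue interaction
    networks with betweenness-centrality hotspot calling, Girvan-Newman
    communities, community bridgeness, and mutation-to-hotspot proximity
    mapping. A synthetic-data module generates multi-state kinase-like
    ensembles so the whole pipeline is testable without predictor runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    cluster,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
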