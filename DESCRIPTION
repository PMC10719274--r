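Package: ddtopo
Title: Delay Discounting and Weighted Structural Connectome Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links intertemporal-choice behavior to the topology of weighted
    white-matter structural brain networks. Provides maximum-likelihood
    estimation of hyperbolic discount rates from choice data, Barratt
    Impulsiveness Scale (BIS-11) scoring, connectome construction from
    tractography summary tables (fiber count x mean FA / average region
    volume edge weights), weighted graph metrics (clustering, path length,
    global and local efficiency, degree and betweenness centrality)
    normalized against degree-matched rewired null ensembles to yield
    small-worldness, hub identification, covariate-residualized Spearman
    rank association testing with global and nodal significance regimes,
    a synthetic-cohort generator with plantable brain-behavior effects,
    and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
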