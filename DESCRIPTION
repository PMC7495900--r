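Package: cmvmc
Title: Consensus Multi-View Multi-Objective Clustering for Unsupervised Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a small, non-redundant set of genes (cluster medoids) from
    an expression matrix by simultaneously clustering genes under two similarity
    views - an expression-distance view and a Gene Ontology / protein-interaction
    functional view - with archived multi-objective simulated annealing (AMOSA).
    Candidate solutions encode one medoid string per view plus their consensus;
    objectives are the Xie-Beni validity index of each view's partition and an
    agreement index between the two partitions. Non-dominated consensus
    partitions are ensembled by majority voting, final cluster medoids become
    the selected genes, and a reduced expression matrix is exported for
    downstream sample classification. Includes readers for expression, similarity,
    OBO, GAF and interaction-network formats, internal and external cluster
    validity measures, a planted-structure synthetic data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
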