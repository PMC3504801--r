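Package: TreeDock
Title: Spanning-Tree Genetic Algorithm Assembly of Multi-Subunit Protein
    Complexes from Pairwise Docking Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles multimeric protein complexes from libraries of scored
    pairwise rigid-body docking decoys. A candidate complex is encoded as a
    spanning tree over the subunits in which every edge selects one pairwise
    decoy, and a genetic algorithm with edge-rewiring mutation and
    tree-merging crossover searches this space, de-duplicating each
    generation by greedy RMSD clustering before truncation selection by a
    configurable three-term fitness function (soft van der Waals,
    distance-dependent-dielectric electrostatics, knowledge-based atom
    contacts). Includes greedy shape-score clustering of pairwise decoy
    pools, CAPRI-style evaluation against a native structure (superposed
    C-alpha RMSD, fnat), and a synthetic fixture generator that plants
    near-native transforms in random decoy pools so the whole pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
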