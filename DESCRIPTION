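Package: lcbn
Title: Ligand-Cluster-Based Protein Networks and Exemplar Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters bioactive ligands by 2D-fingerprint similarity with
    affinity propagation, annotates proteins by the ligand clusters they
    bind, builds and compares ligand-cluster-based and sequence-based
    protein similarity networks, and screens query molecules against
    cluster exemplars with group-fusion baselines (MAX, 3NN, MPS) and
    AUC/Friedman benchmarking. Includes a synthetic-data generator with
    planted cluster and community structure so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
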