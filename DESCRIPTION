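Package: fntscreen
Title: Ligand-Based Virtual Screening with Evolved Flexible Neural Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classify compounds as disease-related or not from molecular
    fingerprints and descriptors using a flexible neural tree (FNT): a
    tree-shaped neural network whose internal nodes are weighted-sum
    Gaussian neurons and whose leaves are input features.  Tree topology
    is searched by grammar-guided genetic programming and node parameters
    are tuned by the salp swarm algorithm.  Includes Tanimoto-based
    selection of the least-similar decoys as negative training examples,
    ECFP6/MACCS/physicochemical featurization of SMILES via OpenBabel,
    stratified cross-validation with standard screening metrics, and
    seeded synthetic-data generators for fingerprint and continuous
    fixtures.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
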