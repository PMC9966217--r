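Package: pairscore
Title: Atomic Pair-Count Scoring Functions for Protein-Ligand Binding
    Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Machine-learning scoring functions for protein-ligand binding
    affinity prediction from 3D complex structures. Complexes are represented
    by distance-binned counts of target-ligand atomic pairs (hydrogen
    included), regressed onto affinities (pKd, pKi, or negated docking
    scores) with a small fully connected neural network trained by
    mini-batch ADAM. Provides the surrounding evaluation machinery:
    horizontal (random) and vertical (held-out protein) benchmark splits,
    leave-one-target-out protocols, per-target scoring functions,
    repeat-averaged Pearson correlation and mean squared error, learning
    curves, descriptor and architecture scans, a ligand molecular-weight
    linear baseline, and a synthetic complex-database generator with
    planted structure-affinity relationships for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'affinity.R'
    'metrics.R'
    'featurizer.R'
    'fcnn.R'
    'model-io.R'
    'mw-baseline.R'
    'fixtures.R'
    'splits.R'
    'evaluate.R'
    'cli.R'
    'complex-io.R'
    'pairscore-package.R'
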