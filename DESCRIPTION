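Package: MiniDock
Title: Desk-Scale Molecular Docking with Empirical Scoring, CNN Rescoring
    and Covalent Docking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained molecular docking stack at desk scale.
    Ligand poses are sampled with Markov chain Monte Carlo chains inside a
    user-defined box, locally minimized against an AutoDock-Vina-form
    empirical scoring function, and rescored with convolutional neural
    networks operating on multi-channel grids of Gaussian atom-type
    densities. Includes a covalent docking mode that bonds a
    SMARTS-selected ligand atom to an addressed receptor atom and samples
    only internal torsions, knowledge distillation of a CNN ensemble into
    a single fast scorer, and the pose and virtual-screening evaluation
    metrics (TopN, ROC AUC, EF1%, nEF1%) used to judge docking programs.
    Synthetic receptor/ligand fixture generators make the whole pipeline
    runnable and testable without any external dataset.
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    ChemmineR,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
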