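Package: mltsa
Title: Machine-Learning Transition-State Analysis for Ligand Unbinding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for studying ligand unbinding from receptors
    with short molecular-dynamics trajectories. Implements the adaptive
    interacting-pair collective variable (CV) used to steer unbinding with a
    monotone harmonic restraint schedule, IN/OUT labeling of unbiased
    "downhill" trajectories with transition-state bisection by committor,
    six feature-set builders (interatomic-distance shells, per-residue
    minimum distances, tracked water distances, Cartesian-coordinate PCA),
    and machine-learning transition-state analysis (MLTSA): replica
    ensembles of multilayer-perceptron and gradient-boosted-tree
    classifiers with relative accuracy drop (RAD) and Gini relative feature
    importance (RFI), aggregated per residue. Ships seeded synthetic-data
    generators (pseudo-atom receptor/ligand/water trajectories and
    overdamped-Langevin double-well committor ensembles with planted
    informative features) so the whole pipeline is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
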