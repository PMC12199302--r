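Package: rcoptim
Title: Committor-Based Reaction Coordinate Optimization for Two-State
    Conformational Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and optimize a reaction coordinate for a
    two-state conformational transition from molecular simulation data.
    Implements trajectory featurization (persistent residue contacts,
    smooth coordination numbers, helical-turn centre-of-mass distances),
    SVM- and PCA-based collective variables, committor estimation by
    trajectory shooting, logistic least-squares reaction-coordinate
    optimization with Monte-Carlo feature selection and bootstrap
    coefficient finalization, umbrella-sampling free-energy profiles via
    WHAM, transition-time statistics with an Eyring-Polanyi rate check,
    and ion-permeation conductance counting. A self-contained overdamped
    Langevin benchmark with an exact one-dimensional committor oracle
    makes every stage testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
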