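Package: cogmapr
Title: Entorhinal-Hippocampal Cognitive Map Building with Multi-Scale Grid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-scale continuous-attractor grid-cell modules for
    velocity-driven path integration, learns place-cell spatial codes from
    them by competitive Hebbian learning, scores hexagonal firing patterns
    (rate maps, spatial autocorrelograms, gridness), detects loop closures
    with a hierarchical visual template tree over RGB-D scene features,
    builds and relaxes topological experience maps, and plans paths with a
    grid-cell-guided multi-scale RRT*. Ships synthetic generators for
    foraging trajectories, drifting loop odometry, procedural RGB-D scene
    streams, and obstacle workspaces so the full pipeline runs without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
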