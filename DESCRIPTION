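Package: slabhinge
Title: Interfacial Structure and Water-Transport Mechanisms in Biphasic Slabs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of water/amphiphile (e.g. octanol) liquid/liquid interfaces
    from molecular-dynamics-style trajectories: intrinsic-surface detection (ITIM
    probe-sphere layers with a density-cluster correction, and the
    Willard-Chandler instantaneous surface with its area), geometric
    hydrogen-bond network graphs and cutoff clusters, five-region layer
    assignment, orientation/density profiles, two-dimensional radial
    distribution functions and excess coordination numbers, bilayer-island
    detection, transport-event detection and mechanism classification
    (diffusion, stochastic flipping, collective hinge transport), Arrhenius
    barrier estimation, Kirkwood-Buff interfacial tension from pressure-tensor
    series, and Langevin dynamics on a constrained double-well potential of
    the hinge transport coordinate. A synthetic-slab generator with planted
    ground truth stands in for MD output so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
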