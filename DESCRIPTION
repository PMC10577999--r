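Package: antarena
Title: Langevin Simulation and Trajectory Analysis of Confined Ant Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the movement of individual ants confined to a square
    arena with a discrete-time Langevin model: anisotropic Laplace-distributed
    velocity impulses applied in the body frame, a linear drag force and a
    constant forward drive, with a stop-at-wall boundary protocol. Provides
    the closed-form equilibrium speed distribution of the unbounded model,
    exact samplers and maximum-likelihood estimators for the impulse law, and
    the trajectory-analysis pipeline used to parameterize and validate the
    model from tracked positions: velocity differencing, transverse and
    longitudinal velocity-change decomposition, per-speed-bin fits, drag and
    drive parameter recovery, occupancy and velocity distribution maps,
    near-wall density asymptotics, and boundary residence-time statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
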