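Package: vascpat
Title: Stochastic Reaction-Diffusion Simulation of Plant Stem Vascular Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie SSA on a voxel lattice,
    reaction-diffusion master equation) of activator-substrate Turing patterning
    in plant stems, including carrier-mediated longitudinal transport with
    Michaelis-Menten saturation, an inhibitor-based zonation mechanism, and an
    apical source-sink variant. Domains are 2D disc cross-sections and 3D
    cylindrical stems with zero-flux boundaries. Ships a deterministic
    finite-difference integrator of the Gray-Scott-Schnakenberg equations as a
    mean-field reference, linear-stability (dispersion relation) analysis,
    pattern quantification (supra-threshold spot detection, radial zonation,
    stationarity), diffusion-rate sweeps, presets for named model families
    (HB, HBP, HBPM, HBPMA and stele patterns), seeded checkpoint/resume, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
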