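Package: cochleafield
Title: Volume-Conduction Modelling of Cochlear-Implant Current Spread
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds parametric synthetic cochlea geometries (with or without
    modiolar microstructures), meshes them into labeled tetrahedral volume
    meshes, solves the quasi-static volume-conduction (Laplace) problem with
    current-controlled monopolar stimulation, floating inactive contacts and
    an extracochlear ground, reconstructs auditory nerve fiber trajectories
    by shortest-path tracing through the nerve-compartment mesh, and computes
    activating-function profiles (length-constant low-pass filtering, first
    and second spatial derivatives), potential decay rates along the spiral
    lamina, detailed-versus-simplified model comparisons, and intracochlear
    voltage-spread telemetry emulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
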