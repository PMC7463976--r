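Package: poreflow
Title: Continuum Electrokinetic Simulation of Particle Translocation Through Solid-State Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled Poisson-Nernst-Planck-Stokes finite-element solver for the
    electrokinetic transport of a charged capped-cylindrical particle (a rigid
    surrogate for a short double-stranded DNA fragment) through a solid-state
    nanopore. Provides graded unstructured meshing of the axisymmetric pore
    geometry, a Picard-coupled steady solver for potential, ion concentrations
    and creeping flow, Maxwell- and hydrodynamic-stress force integration,
    force-free (quasi-static) translocation velocities, ionic current and
    current-deviation observables, trajectory sweeps reproducing field-strength
    and particle-length studies, and closed-form electrokinetic benchmarks
    (Debye-Hueckel, Grahame, Poiseuille, Helmholtz-Smoluchowski) used as
    verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
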