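Package: mechpath
Title: Transition Path Sampling, Reaction Coordinate Discovery and Rate
    Constants on Toy Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for the rare-event analysis used to
    resolve enzyme reaction mechanisms: flexible-length aimless-shooting
    transition path sampling, inertial likelihood maximization for
    reaction-coordinate discovery, committor-probability histogram
    validation, umbrella sampling with multistate Bennett acceptance
    ratio (MBAR) free-energy profiles, reactive-flux transmission
    coefficients, and Eyring rate constants.  The stochastic dynamics
    engine is a BAOAB Langevin integrator over analytic toy potentials
    (1D/2D double wells and high-dimensional linear-combination
    landscapes) that emulate the barrier-crossing statistics of QM/MM
    trajectories, so every stage of the workflow can be exercised and
    validated end to end in minutes on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
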