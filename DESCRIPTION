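Package: srlatch
Title: Multicellular Set-Reset Latch Simulator for Engineered Yeast Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic ODE simulator of a four-cell yeast consortium that
    implements a 1-bit set-reset (SR) latch through two orthogonal alpha-factor
    pheromones acting as intercellular wires. Provides the circuit model with
    its tunable control points (prepro alpha-factor transcription rate,
    repressor efficiency, pathway-activated repressor production, and medium
    clearance), piecewise-constant input protocols with pre-equilibration, an
    adaptive L-stable stiff integrator, flip-flop quality statistics combining
    response fidelity and memory persistence on a Pareto weight, simulation
    based bistability/monostability classification with transient memory
    times, and 1-D/2-D parameter-sweep drivers producing amplitude-normalized
    quality maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
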