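Package: isvor
Title: Rumor Diffusion on Networks with Variation and Silence (ISVOR Model)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and stability analysis of the ISVOR
    (Ignorance-Spreader-Variation-Oyster-Recovery) compartmental model of
    online rumor diffusion, in which a rumor mutates into variant versions
    and individuals may fall temporarily silent before forgetting or
    resuming spreading.  Provides the mean-field ordinary differential
    equation system with equilibrium enumeration, Jacobian/Hurwitz
    stability analysis and threshold intervals; a seeded discrete-time
    agent-based Monte-Carlo simulator on Watts-Strogatz small-world and
    Barabasi-Albert scale-free networks with an exact small-graph
    transition oracle; SIR, SEIR and Twin-SIR network baselines; and
    scripted parameter-sweep experiments with common-random-number
    coupling and peak-diffusion summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
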