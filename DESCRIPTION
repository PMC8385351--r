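Package: BondGraphMet
Title: Energy-Based Bond-Graph Modelling of Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts stoichiometric models of biochemical reaction networks
    into energy-consistent bond-graph models. Provides chemostat/flowstat
    constrained pathway decomposition via exact integer null spaces, energy
    balance analysis, thermodynamically safe parameter estimation from
    steady-state measurements (quadratic programming), and dynamic simulation
    of the resulting mass-action and reversible Michaelis-Menten kinetics.
    Reads SBML Level 3, COBRA-style JSON and a plain reaction-list dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    deSolve,
    jsonlite,
    yaml,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
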