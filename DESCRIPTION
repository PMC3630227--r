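Package: plasmidCNC
Title: Multi-Scale Modelling of Plasmid Copy-Number Control Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic and stochastic multi-scale models of copy-number
    control (CNC) among non-conjugative bacterial plasmids. A single-cell
    deterministic layer couples host biomass growth to autonomous plasmid
    replication, builds the parent-to-daughter copy-number generation map and
    locates its fixed points, stability and fold bifurcation (the edge of
    plasmid stability). A stochastic multicellular engine simulates
    asynchronous cell growth, Poisson plasmid replication with mutation of the
    three heritable plasmid traits (selfishness, policing and obedience),
    binomial segregation at division, cell death and neutral population
    regulation. Scripted experiment drivers reproduce homogeneous-strain
    fitness landscapes, obedience sweeps, trait co-evolution, policing-cost
    sweeps, comparisons between individual and collective restraint, and
    invasion analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
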