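Package: spinesim
Title: Moving-Boundary Simulation of Dendritic Spine Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-dimensional moving-boundary simulation of actin-driven
    dendritic spine enlargement during structural long-term potentiation.
    Couples reaction-transport dynamics of actin filament barbed ends,
    Arp2/3 and cofilin on a cubic lattice to a triangulated spine membrane
    that evolves under Helfrich bending forces and the protrusive force of
    actin polymerization, mediated by a signed-distance repulsive potential.
    Includes the non-spatial kinetic model used to constrain influx and
    turnover parameters from normalized fluorescence time series, a
    synthetic-trace generator, scenario presets for stimulus perturbation
    experiments, and observables (volume, area, neck/head radius, force
    totals, force-velocity pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
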