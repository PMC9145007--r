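Package: retromi
Title: Retroactivity and Information Transmission in Enzymatic Signaling Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how retroactivity -- the load that downstream binding
    sites exert on an upstream enzymatic signaling circuit -- degrades
    information transmission. Five circuit topologies (isolated SISO, SISO
    with N downstream targets, isolated MIMO, MIMO with N downstream targets,
    and two SISO systems sharing a downstream pool as a multiple-access
    channel) are modeled as mass-action reaction networks. In the low
    molecular count regime the stationary chemical master equation is solved
    exactly on the enumerated microstate space, the input/output relation is
    reduced to a Z-channel, and mutual information, channel capacity and
    capacity bounds are computed. Closed-form retroactivity constants are
    provided together with their validity regimes, checked against the exact
    solver. In the high molecular count regime the linear noise approximation
    yields steady-state means from the rate equations and stationary
    covariances from a Lyapunov equation, giving Gaussian-channel capacities.
    A Gillespie stochastic simulation oracle and a synthetic parameter
    generator support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'reaction-networks.R'
    'cme.R'
    'analytic-constants.R'
    'lna.R'
    'experiments.R'
    'info-metrics.R'
    'retromi-package.R'
    'ssa.R'
    'synthetic-data.R'
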