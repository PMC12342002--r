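Package: crneq
Title: Equilibrium Analysis of Mass-Action Reaction Networks for In-Silico
    Mutation and Drug-Dosage Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling intracellular signalling as mass-action
    chemical reaction networks and for studying how their equilibria shift
    under genetic perturbations and targeted drugs.  Networks are described
    in a plain-text interchange format; the package extracts semi-positive
    moiety conservation laws, computes equilibria on a stoichiometric
    compatibility class either by stiff ODE integration or by a projected
    Newton root-finder, applies loss- and gain-of-function mutation
    operators, augments networks with competitive or allosteric inhibitors
    (with optional first-order degradation and scheduled administration),
    and summarises mutation and drug effects through relative-difference
    profiles, a modified geometric mean, and one- or two-dimensional dose
    scans.  A seeded generator of MAPK-cascade-like toy networks provides a
    fully reproducible testbed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
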