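Package: efmcost
Title: Cost-Vector Analysis of Elementary Flux Modes Under Enzyme Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for growth-rate maximization in small kinetic metabolic
    models subject to weighted enzyme-concentration constraints. Provides
    enumeration of Elementary Flux Modes (EFMs) of irreversible stoichiometric
    networks, per-EFM enzyme cost vectors at given metabolite concentrations,
    a vertex-exact linear program over EFM weights, an outer optimization over
    internal metabolite concentrations, and diagnostics for the extremum
    principle that bounds the number of flux-carrying EFMs by the number of
    active enzyme-expression constraints. Ships coarse-grained case-study
    models of overflow metabolism and of the Lactococcus lactis fermentation
    switch, a seeded generator of random model instances, perturbation
    experiments on enzyme pools and catalytic rates, a proportionality
    diagnostic for chemostat data, and a JSON model format with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
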