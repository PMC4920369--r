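Package: gencue
Title: Genetic Cues of Relatedness and Social Evolution in Two-Habitat Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation tools for social evolution with genetic
    cues of relatedness in a two-habitat population. Provides the closed-form
    payoff machinery of a group-structured public-goods game, deterministic
    resident dynamics over (habitat, cue-allele) classes, mutant-modifier
    invasion analysis via projection matrices (invasion fitness, reproductive
    values, selection gradients), coexistence-region scans and gradient-path
    searches for dimorphic evolutionary equilibria, a forward-time
    individual-based simulator with evolvable modifier architectures, and
    information metrics quantifying how much a cue allele tells an individual
    about its habitat.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
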