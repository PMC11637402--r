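Package: bgsisland
Title: Background Selection, F(ST) and Diversity in Island Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Theory and forward simulation of background selection in a
    finite island model. Solves a quantitative-genetic model of linked
    purifying selection for the local strength of background selection
    (B), including a migration effect by which emigration truncates the
    cross-generational association between neutral and deleterious
    alleles, and weak-selection corrections that account for fixation of
    deleterious alleles by drift. Turns local B into metapopulation
    predictions of F(ST), G(ST), global effective population size and
    nucleotide diversity, and validates them with a forward-time
    Wright-Fisher island-model simulator with multiplicative selection,
    recombination and migration, plus Hudson-style diversity and
    differentiation estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
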