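Package: breedopt
Title: Stochastic Simulation of Optimized Mate Selection in Cattle Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of a cattle-like breeding program:
    genome and quantitative-trait simulation (recombination, mutation,
    burn-in to mutation-drift equilibrium), GBLUP genomic evaluation,
    mate allocation by linear programming over a selection index with an
    inbreeding penalty, optimal contribution selection (maximum-gain and
    minimum-kinship formulations), and truncation-selection controls.
    Tracks genetic gain, average genomic kinship, QTL effect variance and
    observed heterozygosity across generations of selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
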