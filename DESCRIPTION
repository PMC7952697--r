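Package: premate
Title: Premating Reproductive Isolation from Copulating-Pair Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing mating patterns in field surveys of copulating
    pairs sampled alongside quadrat censuses, developed around the cryptic
    sympatric periwinkle species of the subgenus Littorina (Neritrema). Fits a
    null model of random mating in which passive-partner frequencies come from
    the census composition and active-male frequencies from the pairs
    themselves, and derives from it the Fidelity Index (prevalence of
    conspecific-female matings) and a precopulatory isolation index for species
    pairs, both with bootstrap inference. Also provides presence/absence
    clustering of observed partner-type combinations (simple mismatch
    coefficient + UPGMA), permutation and Monte-Carlo tests of size-assortative
    mating and spatial segregation by size, and a synthetic-data generator with
    tunable species preference and size assortment so that every stage of the
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
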