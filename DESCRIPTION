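Package: founderdrift
Title: Individual-Based Simulation of Founder Effects on Microsatellite
    Diversity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of a large-mammal
    population founded by very few individuals, with overlapping
    generations, age-structured survival and fecundity, and Mendelian
    transmission of multi-locus microsatellite genotypes.  Implements the
    establishment of the Finnish white-tailed deer population (founded in
    1934 by three females and one male) under alternative assumptions
    about founder genetic composition, and contrasts the simulated
    retention of heterozygosity and allelic richness with classic
    heterozygosity-decay theory.  Also provides estimators of expected
    and observed heterozygosity and allelic richness, a tie-corrected
    Mann-Whitney comparison of per-locus diversity between populations,
    Genepop and wide-CSV genotype input and output, and a
    Hardy-Weinberg genotype sampler for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
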