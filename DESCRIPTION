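Package: apisim
Title: Individual-Based Simulation of Honeybee Populations and Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic, individual-based simulation of honeybee (Apis
    mellifera) populations and breeding programs. Simulates founder genomes
    with a structured coalescent, haplodiploid inheritance with a
    non-recombining complementary sex determination (csd) locus, queens with
    polyandrous mating and stored fathers, colonies with castes (queen,
    fathers, workers, drones, virgin queens) and colony events (swarming,
    splitting, supersedure, collapse, downsizing, combining), apiaries of
    multiple colonies, and additive quantitative genetics with correlated
    queen- and worker-effect traits mapped to colony-level values. Includes
    genomic data extraction (haplotypes, genotypes, identity-by-descent) and
    VanRaden genomic relationship matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
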