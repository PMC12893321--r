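Package: hylopop
Title: Conservation Population Genomics Toolkit for Small Gibbon Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for noninvasive (fecal) conservation genomics of small
    primate populations: genotype quality control for low-input samples
    (allele-dropout estimation from parent-offspring trios, duplicate-library
    discordance, coverage-saturation modelling), core population-genetic
    statistics (heterozygosity, realized and masked genetic load, runs-of-
    homozygosity inbreeding, GC content at fourfold-degenerate sites as a
    recombination proxy, pedigree-based crossover counting), a folded-SFS
    balancing-selection scan, an individual-based non-Wright-Fisher forward
    simulator of age-structured, polygynous gibbon demography with a gamma
    distribution of deleterious fitness effects, and a population viability
    analysis comparing lineage-cross mating strategies. Synthetic-data
    generators with exact truth records make every stage testable without
    restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
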