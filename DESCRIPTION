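Package: pondmix
Title: Hybrid-Zone Admixture, Cline and Demographic Inference for
    Multilocus Population Genetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing secondary contact zones between
    divergent lineages with co-dominant multi-allelic markers
    (microsatellites) and a maternally inherited sequence marker
    (mtDNA).  Provides an expectation-maximisation admixture model
    with Evanno delta-K cluster-number selection, simulation of hybrid
    classes (F1, F2, backcrosses) for calibrating ancestry thresholds,
    equilibrium geographic cline fitting by Metropolis-Hastings MCMC
    with AIC selection over the classical 15-model family, rejection
    approximate Bayesian computation under explicit admixture-pulse
    coalescent scenarios, diversity and divergence statistics
    (heterozygosities, allelic richness, Weir-Cockerham F_ST, AMOVA),
    minimum-spanning haplotype networks, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
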