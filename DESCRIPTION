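Package: contactzone
Title: Population-Genetic Analysis of Secondary Contact Zones from
    Codominant Multilocus Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing secondary contact zones between divergent
    populations using codominant multilocus genotypes (microsatellites).
    Provides Genepop input/output, per-locus summary statistics and quality
    control (heterozygosity, Weir-Cockerham F-statistics with jackknife
    confidence intervals, exact Hardy-Weinberg tests, likelihood-ratio
    linkage-disequilibrium tests, null-allele screening), Bayesian and
    EM admixture estimation for two clusters, hierarchical analysis of
    molecular variance (AMOVA) with permutation tests and iterative removal
    of admixed samples, hybrid-zone bimodality testing by genotype
    simulation under mechanical-mixing and hybrid-swarm models, geographic
    cline fitting by twice-broken-stick regression with
    coincidence-concordance outlier detection, FST-outlier screening
    against a coalescent island-model envelope, and a synthetic contact-zone
    data generator with known truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    vegan,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
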