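# contactzone

Population-genetic analysis of secondary contact zones from codominant
multilocus genotypes (microsatellites), built around the situation found
in eastern oysters of the western Gulf of Mexico: two anciently diverged
populations (multilocus Fct near 0.4) that meet along a short stretch of
coastline, where some reefs carry mechanical mixtures of both
populations rather than hybrid swarms.

The package answers four questions a contact-zone study asks of a
genotype table:

1. **How divergent are the populations, and which samples are admixed?**
   Two-cluster admixture estimation (Gibbs sampler or deterministic EM;
   unsupervised or with flanking reference populations), hierarchical
   AMOVA on allele-identity distances with permutation tests
   (`Fct = a/(a+b+c)`, `Fsc = b/(b+c)`), and the iterative procedure
   that removes the most admixed sample until the among-site component
   is no longer significant, classifying every site as northern,
   southern or mixed by its mean admixture score Q.
2. **Are mixed reefs hybrid swarms or mechanical mixtures?** Genotypes
   are simulated under both models (Hardy–Weinberg draws from pooled
   frequencies versus pure parental draws at the observed mixing ratio),
   scored against the same references, and compared with the observed
   admixture-score distribution by two-sample Kolmogorov–Smirnov tests;
   a ten-category hybrid-index histogram summarizes bimodality.
3. **Do individual loci behave differently from the genome?** Geographic
   clines of allele frequency on latitude are fitted with the
   "twice-broken-stick" model (flat plateaus flanking a linear
   transition; midpoint and slope from the fitted parameters), loci are
   screened for clinal behaviour (Mantel isolation-by-distance plus an
   F-test of the broken-stick improvement over a line), and outliers in
   the coincidence–concordance plane (midpoint, log |slope|) are flagged
   by bivariate kernel-density contours with a biased-cross-validation
   bandwidth matrix. A separate FST-outlier scan simulates the neutral
   FST–heterozygosity cloud under a 100-deme island-model coalescent
   anchored at the trimmed multilocus Weir–Cockerham theta.
4. **Did the zone move?** Mean cline-midpoint displacement between two
   datasets, in kilometres (positive = northward).

Everything is exercised end-to-end on synthetic data from the built-in
contact-zone generator (`sim_config()` / `simulate_dataset()`), which
produces Genepop-compatible datasets with known truth: parental
frequencies drawn by the Balding–Nichols construction at a target Fct,
sites planned along a latitudinal transect with pure, mechanically
mixed, hybrid-swarm or F1 composition, and optional null alleles,
miscalls and missingness.

Standard quality control is included: observed/expected heterozygosity,
Weir–Cockerham F-statistics with jackknife confidence intervals, exact
Hardy–Weinberg tests (Monte-Carlo, conditional on allele counts), the
Excoffier–Slatkin EM likelihood-ratio test of linkage disequilibrium for
unphased genotypes, sequential Bonferroni (Holm) correction, a
Chakraborty null-allele screen, and duplicate-run genotyping error
rates.

## Worked example

```r
library(contactzone)

## a 25-site contact zone: 11 southern, 7 mechanically mixed, 7 northern
## reefs of 20 oysters each, 11 microsatellites, parental Fct 0.4
plan <- zone_site_plan(mixed_model = "mechanical_mix")
sim  <- simulate_dataset(sim_config(site_plan = plan, seed = 21))

qm   <- fit_admixture(sim$dataset, mode = "em")
zone <- iterative_admixed_removal(sim$dataset, qm, seed = 5)
print(zone)
#> zone_partition: 8 northern, 11 southern, 6 mixed site(s)
#> removal order: Z17 -> Z13 -> Z16 -> Z12 -> Z14 -> Z15
#> final Fct = 0.3532 (p = 0.000999), Fsc = 0.0007 (p = 0.4116)

refs  <- list(northern = plan$id[plan$composition == "pure_north"],
              southern = plan$id[plan$composition == "pure_south"])
mixed <- plan$id[plan$composition == "mechanical_mix"]
sup   <- fit_supervised(sim$dataset, refs)
bimodality_test(sim$dataset, sup, mixed, refs, n_sim = 1000, seed = 4)
#> Hybrid-zone bimodality test (two-sample Kolmogorov-Smirnov)
#>   vs mechanical mixing: D = 0.047, p = 0.9463
#>   vs hybrid swarm:      D = 0.533, p = 0
#>   hybrid index histogram: 63 2 0 0 0 0 0 0 1 74
#>   bimodality descriptor = 137.00 (>1 bimodal)
```

Reading: the removal procedure flagged six of the seven planted mixed
reefs; the seventh (northern fraction 0.65) drew a sample mean Q of
0.72, just above the 0.70 mixed threshold — with 20 individuals per
reef and mechanically mixed composition the mean Q of a strongly
uneven mixture is noisy, which is exactly why the zone design spreads
mixing ratios around one half. After removal the remaining sites show
Fct ≈ 0.35 between regions with no residual among-site structure
(Fsc p = 0.41), and the admixture-score distribution on the mixed reefs
is strongly bimodal — consistent with mechanical mixing (KS p = 0.95)
and inconsistent with a hybrid swarm (KS p < 10⁻⁵).

`run_pipeline(pipeline_config(...))` chains all stages (QC → admixture →
zone partition → HWE/LD tables → bimodality → clines and Co-Co →
FST outliers → optional cline shift and spatfall frequencies) and writes
a CSV/JSON report bundle whose bytes are fully determined by the
configuration and seed.

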