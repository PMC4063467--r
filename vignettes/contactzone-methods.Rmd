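---
title: "Models and methods behind contactzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind contactzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`contactzone` analyses secondary contact zones — places where two
anciently diverged populations of a sessile marine invertebrate (the
motivating system is the eastern oyster in the western Gulf of Mexico)
meet again — from codominant multilocus genotypes. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the methodology was genuinely open.

## The synthetic contact zone

Because every inferential stage is validated against data with known
truth, the generator is first-class code, not a test fixture.

**Divergence model.** `draw_divergent_frequencies()` draws, per locus,
an ancestral frequency vector from a flat Dirichlet and the two parental
vectors from `Dirichlet(p_anc * (1 - F) / F)` — the Balding–Nichols
construction, chosen because it maps one parameter to an expected
divergence level. The realized multilocus divergence is measured by
`wright_fct()`, the *variance-component* (theta-style) parameterization:
per allele `s2 = sum((p_i - pbar)^2)/(r - 1)` over `pbar(1-pbar) + s2/r`,
as a ratio of sums over alleles and loci. This is the quantity that the
Weir–Cockerham and AMOVA estimators converge to; the familiar
`(Ht - Hs)/Ht` form is *not* used because for two regions it sits near
half the variance-component value and would make the generator's target
incommensurate with the pipeline's own estimates. Under Balding–Nichols
the expectation of the variance-component index equals `F` exactly. A
draw is accepted when the realized value is within ±0.05 of the target
(bounded retries), so "simulated at Fct 0.4" means what the AMOVA will
report.

**Site plans.** `macro_site_plan()` mirrors a broad transect: ten reefs
of 45 individuals between 26.0° and 29.8° N, five per region.
`zone_site_plan()` mirrors a fine-scale zone: 25 reefs of 20
individuals — 11 southern, 7 mixed with northern fractions
0.35–0.65, 7 northern. Mixed-reef composition is either
`mechanical_mix(r)` (each individual belongs wholly to one population,
northern with probability `r` — the Wahlund configuration) or
`hybrid_swarm(r)` (each allele an independent draw from the pooled
frequencies `r·pN + (1-r)·pS`); `f1_only` draws one allele from each
parent. `plant_cline()` sets `r` along a logistic in latitude with known
midpoint and slope.

**Noise.** Null alleles follow the hidden-allele model used by standard
microsatellite QC software: each drawn allele is independently null with
the per-locus rate; visible/null heterozygotes are recorded as visible
homozygotes, null/null as missing. Genotyping error replaces an allele
with a uniformly chosen *neighbouring* fragment-size label (miscalls are
near-misses on a sequencer, not arbitrary). Missingness is per genotype.
All three default to zero: noise is opt-in, and tests that need it turn
it on explicitly.

What the generator does **not** emulate: linkage between loci within a
population, allele-frequency clines caused by selection (clines arise
only through composition gradients), age structure, and spatially
correlated sampling. Passing tests therefore demonstrate correctness of
the estimators under the stated sampling models, not robustness to every
feature of real reef data.

## Admixture estimation (K = 2)

The model is the standard two-cluster admixture model with
*uncorrelated* cluster frequencies: each allele copy of individual *i*
originates from cluster *k* with probability `Q[i,k]` and is then a draw
from that cluster's frequency vector. Priors are `Dirichlet(1)` on
frequencies and a symmetric `Dirichlet(alpha = 1)` on each Q row; alpha
is fixed, not inferred — with two strongly diverged clusters the
posterior is insensitive to it, and fixing it removes a tuning
dimension. The correlated-frequency prior used by some reference
software is deliberately omitted: at divergence near 0.4 its benefit is
negligible and the simpler model is fully specifiable.

Two inference modes:

* `mode = "gibbs"`: Gibbs sweeps over copy origins, cluster frequencies
  and Q; the result is the posterior mean after burn-in (defaults 5,000
  burn-in / 45,000 sampling — a desk-scale tenth of a classic
  half-million-iteration run; raise them in config for publication
  work). Convergence is checked by split-half agreement of the
  posterior-mean Q (flagged, not failed, when >5% of individuals differ
  by >0.05).
* `mode = "em"` (the pipeline default): deterministic block relaxation
  to the maximum-likelihood fixed point, initialized from a
  latitude-split so the labels are stable.

The two modes estimate slightly different summaries: the posterior mean
carries Beta-prior shrinkage of order `1/(2L + 2)` toward 0.5 plus a
small soft-assignment effect, while the EM fixed point is the MLE.
With enough allele copies per individual (about 20 loci and up) they
agree within 0.05 on well-separated data; at 11 loci the systematic gap
for a pure individual is about 0.04–0.08. The EM mode is the default
because the pipeline thresholds (0.70/0.80 on *site means*, which
average the shrinkage away) are insensitive to the difference and the
EM is orders of magnitude faster and exactly reproducible.

Label switching is resolved geographically: cluster 1 is anchored to the
majority cluster of the northernmost site, so `Q1` always reads as
northern ancestry. `fit_supervised()` estimates cluster frequencies from
flanking reference sites (posterior mean under a flat Dirichlet) and
scores every individual against them by a per-individual EM; reference
allele values are kept on the full reference scale rather than
renormalized over the query's allele subset, which would distort the
likelihood ratio.

## AMOVA and the zone partition

`amova()` partitions allele-identity distances (0/1 per locus, summed)
into among-region, among-site-within-region and within-site components
by the standard sums-of-squares decomposition, with
`Fct = a/(a+b+c)` and `Fsc = b/(b+c)`. Significance: whole sites are
permuted among regions for Fct; individuals are permuted among sites
within regions for Fsc; p-values include the observed configuration
(`(b+1)/(B+1)`, default 1,000 permutations). With few sites the Fct
null is coarse — ten sites in a 5/5 split admit only 252 distinct
partitions — so whenever complete enumeration is no more work than the
requested permutation count, the Fct test is computed exactly over all
assignments (for that design the smallest achievable p is 2/252, about
0.008).
Loci with no scored copies contribute nothing; individuals with no
scored genotypes are excluded with a message. When every region has a
single site, or there is no within-region variation at all, Fsc is
undefined and reported as `NA` rather than a number.

`iterative_admixed_removal()` starts from the majority-cluster region
assignment, and while Fsc is significant at `alpha` (0.05 by default —
the conventional level; the removal criterion "no longer significant"
needs one) removes the remaining site with the smallest `max(mean Q)`
among sites below the mixed threshold (0.70), ties broken by site id for
reproducibility. Removed sites are `mixed`; the rest are classified by
`classify_site()` (pure above 0.80; between the thresholds the majority
label is kept with a provisional flag). During the loop only the Fsc
permutation test is run; the final model is re-run with both tests.

## Hybrid-zone bimodality

The question is whether mixed-reef genotypes reflect co-settlement of
two non-interbreeding populations (bimodal admixture scores, Wahlund
heterozygote deficits, strong two-locus disequilibrium) or random mating
within the zone (unimodal scores, Hardy–Weinberg at pooled
frequencies). The pipeline first checks that the mixed reefs share one
admixture-score distribution (Kruskal–Wallis on Q1, chi-square
approximation with ties correction), then pools them and simulates both
models at matched size: the mechanical model from the flanking groups'
pooled frequencies at each reef's observed mean-Q mixing ratio (the
stated estimator — not re-fit), the swarm model from the mixed samples'
own pooled frequencies. Observed and simulated individuals are scored
against the *same* reference frequencies, and the distributions compared
by two-sample Kolmogorov–Smirnov tests; with K = 2, Q1 carries all the
information. The simulated side is a genuine two-sample comparison
(rather than a one-sample test against the simulated CDF) because at
moderate `n_sim` the two converge and the two-sample form is honest
about simulation noise.

`hybrid_index_histogram()` bins Q1 into `(0, 0.1], ..., (0.9, 1]` (zero
goes into the first bin; 0.5 — an F1 — falls in bin 5) and reports the
outer-to-central bin-count ratio as a bimodality descriptor (>1
bimodal).

## Clines and the Co-Co plane

For each locus the *tracked allele* is the one with the largest absolute
frequency difference between the northernmost and southernmost sites.
The cline model is the twice-broken stick: constant `p_south` south of
`lat_south_edge`, constant `p_north` north of `lat_north_edge`, linear
in between; the midpoint is the centre of the linear segment (where the
fitted frequency crosses the plateau mean) and the slope is per degree
latitude, positive northward. Given the edges the plateaus enter
linearly, so fitting profiles the residual sum of squares over edge
pairs: a deterministic grid over site latitudes and their midpoints
replaces the visual initialization an analyst would otherwise supply,
and Nelder–Mead refines the edges on `(south edge, log width)`. On
noise-free data with at least two sites inside the transition the
recovery is exact; *edge identifiability requires interior sites*, and
with none the zero-residual solution is not unique. Degenerate fits
(collapsing edges, coinciding plateaus) are errors, not numbers.

A locus is *clinal* when (1) a Mantel test (999 permutations) of
pairwise frequency distance against great-circle distance is significant
and (2) an F-test shows the broken stick improves on a straight line
(2 extra parameters). Both criteria at 0.05.

The Co-Co (coincidence–concordance) analysis places each clinal locus at
`(midpoint, log|slope|)` — natural log, slope floored at 1e-6 — and
flags loci outside the smallest regions holding 95% and 99% of the
kernel-density mass. Three numerical choices matter here:

* **Bandwidth.** The bivariate biased-cross-validation (BCV) criterion
  for an unconstrained Gaussian bandwidth matrix has a closed form for
  Gaussian kernels (`BCV(H) = (4 pi n)^-1 |H|^-1/2 + psi/4` with
  `psi` from pairwise differences), but like its univariate counterpart
  it decays to zero under extreme oversmoothing, so — exactly as
  `bw.bcv` does — the optimization is bounded, here to a window around a
  normal-reference anchor `n^(-1/3) * S`. `S` is a *robust* covariance
  (MAD marginals, Kendall-based correlation) so that the outliers being
  hunted cannot inflate their own smoothing window. On large bivariate
  normal samples the interior BCV minimum is found and sits within 20%
  of the normal reference.
* **Leave-one-out density.** Each point is evaluated under the density
  of the *other* points, so a lone extreme point cannot mask itself.
* **Threshold calibration.** The contour height for mass level L is the
  `(1-L)` quantile of a smoothed-bootstrap null: repeatedly draw n
  points from the leave-one-out mixture and evaluate the leave-one-out
  density of one of them. This reproduces the full estimator under the
  fitted density, including its finite-sample noise — a plain quantile
  of the density over an MC sample ignores that noise and was measurably
  anti-conservative at n near 13, while letting an extreme point
  contribute 1/n of the null mixture let it drag down its own 99%
  threshold. With the per-point null both problems disappear: false
  flags stay at or below the nominal rate and a 10-SD planted outlier is
  caught at both levels.

Welch t-tests compare midpoints and log-slopes between marker classes
(e.g. microsatellites vs allozymes); degenerate zero-variance
comparisons return `t = 0, p = 1` by convention. The temporal shift is
`(mean midpoint_t2 - mean midpoint_t1) * 111.2 km/degree` (mean meridian
arc; configurable).

## FST outliers

The neutral envelope comes from a structured-coalescent simulation of a
100-deme symmetric island model with two sampled demes (50 diploids
each), the published default geometry of the classical
FST-vs-heterozygosity outlier method. Only the embedded jump chain is
simulated — under the infinite-alleles model a mutation event assigns a
fresh allele to the lineage's subtended sample and retires the lineage,
and under the stepwise model it shifts the subtended sample's repeat
offset by ±1, so event order suffices and no branch lengths are needed.
Scaled migration starts at the island-model expectation
`FST = 1/(1 + M (d/(d-1))^2)` and is calibrated by bisection on pilot
simulations until the mean simulated theta (haploid Weir–Cockerham,
ratio of sums) matches the anchor within 0.02. The anchor is the
*trimmed* multilocus theta of the observed data (drop the most extreme
per-locus theta on each side when at least five loci are polymorphic).
Per-locus scaled mutation rates are drawn log-uniformly over
[0.05, 4] so simulated heterozygosities span the observed range;
infinite alleles is the default for microsatellite-rich data at high
divergence, stepwise is available by flag and documented as an
approximation.

Classification is by conditional p-value: the proportion of simulated
loci in the observed locus's heterozygosity window with theta at or
below the observed theta; `low` below 0.025 (balancing-selection
candidates), `high` above 0.975. The windows are **fixed equal-count
bins** (5% of the cloud each), not windows centred on the observed
locus: at divergence near 0.4 under infinite alleles, theta given
heterozygosity is nearly deterministic, and a centred window pins a
neutral locus's theta rank to mid-window, deflating the flag rate to
about 3% instead of the nominal 5%. With fixed bins the observed locus
falls uniformly within its bin and the conditional p-value is
calibrated (measured 5.3% on 2,000 self-model loci). Observed loci whose
heterozygosity falls outside the simulated range are reported
`unevaluable` rather than forced into the nearest bin — at strong
divergence the island model simply cannot produce polymorphic loci of
very low total heterozygosity, a known blind spot of the method.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains the stages in the scientific order (QC and
marker screening; unsupervised admixture; classification and iterative
removal; supervised admixture against the flanking sites; HWE/LD tables
with Holm correction per group; bimodality; clines and Co-Co; FST
outliers; optional second-epoch shift; optional spatfall frequencies),
writing one CSV per stage plus a JSON manifest (config hash, seed,
package version; file names only, so bundles are relocatable). Every
stochastic stage derives a sub-seed from the master seed; two runs with
the same configuration and seed are byte-identical. Stages that need
mixed sites are skipped with an explicit notice when none exist.

One caveat worth knowing: the null-allele screen (mean Chakraborty
estimate < 0.05, the conventional marker-inclusion rule) reads any
heterozygote deficit as nulls. On data containing mechanically mixed
reefs the Wahlund effect triggers it for perfectly clean loci — the two
artefacts are confounded at the level of a single-sample deficit. The
screen is applied at stage 1 as the rule prescribes, and can be turned
off (`drop_failed_loci = FALSE`) when analysing zones where strong
mixing is expected; ideally it is run on pure-population samples, as in
the marker-selection phase of the motivating study.

Default run sizes are desk-scale and are the sizes the test-suite
validation uses: 1,000 AMOVA permutations, 2,000 Monte-Carlo HWE
iterations, 100 LD permutations, 999 Mantel permutations, 2,000–5,000
simulated envelope loci, 500–1,000 simulated individuals per bimodality
model, 20 zone replicates for partition recovery, 50 replicates for the
bimodality power checks, 100 replicate clouds for the Co-Co
calibration. All are arguments, and scale up linearly when more
precision is wanted.

## Known limitations

* K is fixed at 2; model choice over K is out of scope.
* The admixture model ignores linkage; mechanically mixed samples
  violate its assumptions by construction (that violation is exactly
  what the bimodality analysis detects, but individual Q values inside
  mixed reefs should be read as descriptive).
* The cline model is piecewise-linear, not a sigmoid cline-theory fit;
  no barrier-strength or tension-zone parameters are estimated.
* The FST-outlier scan inherits the classical method's assumptions
  (equilibrium island model, independent loci) and its weak power at
  few loci; with 11 markers a "balancing selection" flag is a
  hypothesis, not a finding.
* Jackknife FIS intervals use a normal approximation over sites
  (percentile option available); with few sites they are rough.
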