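---
title: "Inferring recent demography from IBD segment sharing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recent demography from IBD segment sharing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdscape)
```

`ibdscape` turns detected identity-by-descent (IBD) and
run-of-homozygosity (ROH) segments into inferences about recent
demographic history: hierarchical genetic communities, time-stratified
sharing contrasts, effective population size (N~e~) trajectories,
robustness tests, surname-origin enrichment, ancestry classification and
affinity decomposition. This vignette explains the models behind each
stage, the parameters that matter, and the choices made where the design
was genuinely open.

## The coalescent-Poisson segment model

Everything rests on one generative model. Two haplotypes that coalesce
`g` generations ago are separated by `2g` meioses. Over a genome of
genetic length `L` cM split into `K` chromosomes, the number of IBD
segments that survive recombination is modelled as Poisson with mean
`2gL/100 + K` — the `2gL/100` term counts crossover-delimited pieces and
the `+K` offset recognises that each chromosome contributes a segment
even with no crossovers at all. Segment lengths are exponential with
mean `100/(2g)` cM, so long segments are the fingerprint of recent
coalescence. A detector only reports segments at or above a threshold
`m` cM (default 1).

The coalescence time itself follows a discrete-generation
piecewise-constant N~e~ model. Within a population the hazard at
generation `g` is `1/(2N(g))`, giving

$$c(g) = \frac{1}{2N(g)} \prod_{j=1}^{g-1}\Bigl(1 - \frac{1}{2N(j)}\Bigr),$$

and across two populations coalescence is impossible before their split
generation `T` and follows the ancestral trajectory afterwards. The
expected number of detectable segments per haplotype pair with length in
`[u, v)` is then

$$\mu(u,v) = \sum_g c(g)\,\Bigl(\tfrac{2gL}{100} + K\Bigr)\,
  \bigl(e^{-2gu/100} - e^{-2gv/100}\bigr).$$

The generation horizon defaults to `G_max = 300`: at human-scale N~e~
the contribution of deeper generations to segments ≥ 1 cM is negligible
(the `e^{-2g/100}` tail has decayed by more than e^{-6}).

**The simulator** (`simulate_ibd()`, `simulate_roh()`) draws from
exactly this model. Rather than drawing all segments and discarding
those below `m`, it draws thinned counts `Poisson(λ_g e^{-2gm/100})`
and lengths `m + Exp(100/2g)` — an exact equivalence by memorylessness
of the exponential, which keeps simulated cohorts cheap. Segments are
placed on chromosomes with probability proportional to genetic length at
uniform starts, and placements of the same pair may overlap; downstream
statistics use counts and totals, never positional overlap, so this
simplification is inconsequential. What the generator deliberately does
*not* emulate: ancestral-recombination-graph correlations along the
genome, detection error (phase switches, gap splitting), continuous
migration (splits are clean), and selection. Tests passing on this
synthetic data therefore demonstrate correctness of the estimators under
the model's assumptions, not robustness to refinedIBD's error modes on
real genotypes.

**Time proxies.** The canonical length bins `[1,3)`, `[3,5)` and `[5,∞)`
cM act as proxies for roughly 100, 45 and 15 generations ago
(conventionally ~3000, ~1200 and ~450 years). These round year figures
are not one exact generation-time multiple; `bin_to_time()` returns them
as conventional values and accepts an explicit `years_per_generation`
to recompute years as an exact multiple instead. The bins are proxies
with wide time ranges — comparisons between bins should be read as
"older vs more recent", not as dated events.

## Networks and hierarchical communities

`build_network()` connects two samples when at least one segment of
≥ 4 cM (configurable) links any of their haplotypes. The clustering
weight is the **total** cM shared; the **mean** segment length is carried
separately for display and top-k edge export, because the two weights
answer different questions (volume vs recency of sharing).

`filter_relatives()` removes close kin before clustering: while any edge
exceeds `max_total_cM`, the higher-degree endpoint of the first offending
edge (in sorted order) is dropped, which is deterministic and guarantees
the post-condition that no retained edge exceeds the threshold. The
default of 1400 cM corresponds to roughly second-degree kin on a 3500 cM
genome, but the right value is cohort-dependent and should be set
explicitly — published pipelines rarely print theirs.

`recursive_leiden()` runs Leiden clustering (modularity objective,
igraph implementation) on the full network, then recurses into each
community of at least `min_size` members for up to three levels. Labels
are hierarchical paths ("2.1.3"). Communities below `min_size`
(default 30) keep their parent label at deeper levels, so every sample
is labeled at every level — a deliberate choice that keeps downstream
per-level summaries total. The modularity objective and per-level
resolution of 1.0 are defaults, not claims about any published analysis;
resolution is exposed per level because the appropriate granularity is a
scientific decision.

## Time-stratified sharing statistics

`pairwise_sharing()` reports, per community pair and length bin, the
mean segment count and mean total cM **per individual pair, including
pairs that share nothing** — without zero pairs the mean is undefined
for sparsely sharing community pairs and biased everywhere else. This
inclusion is config-exposed only in the sense of being documented; the
zero-inclusive mean is the estimator used throughout.

Confidence intervals are percentile bootstrap over **individuals**, not
pairs: pairs sharing an individual are dependent, so resampling pairs
would understate variance. When a bootstrap resample repeats an
individual, pairs formed from two copies of the same individual are
excluded from the mean (scoring them as zero would bias the bootstrap
distribution downward by the duplicate fraction). 500 replicates by
default; the analysis scripts use 100–200.

Group contrasts ("Irish communities share more in `[1,3)` than English
ones") use Welch's unequal-variance t-test on per-pair totals
(`mean_comparison_test()`), one-sided when directionality is asserted.

**F statistics.** `f_roh()` is total ROH length ≥ 1 cM over `L`.
`f_is()` is `1 − ΣH_o/ΣH_e` over polymorphic SNPs — a ratio of averages,
which is stable when many SNPs are rare; H~e~ carries no sample-size
correction, so with `n` diploids the null expectation sits near
`−1/(2n−1)` rather than exactly 0 (about −0.03 at n = 18, visible in the
analysis-stage output). `hudson_fst()` uses the Hudson estimator as a
ratio of averages with allele-count bias corrections, excluding SNPs
with an undefined denominator; it was chosen for robustness to unequal
sample sizes, and may differ from whatever estimator a given published
supplement used. The joint pattern this module is built to expose:
small-N~e~ populations show inflated F~ROH~ at F~IS~ ≈ 0, separating
drift-driven homozygosity from consanguinity.

## Effective population size from the length spectrum

`fit_piecewise_ne()` maximizes the Poisson likelihood of the observed
spectrum `k_b` over per-epoch log N~e~:

$$\ell(N) = \sum_b \bigl[k_b \log(P\mu_b(N)) - P\mu_b(N)\bigr]
  - \lambda \sum_e (\Delta \log N_e)^2,$$

with `P = 4·C(n,2)` haplotype pairs. Choices and their reasons:

* **Fine bins** default to edges {2,3,4,5,6,8,10,14,20,∞} cM. The three
  coarse time-proxy bins under-determine a five-epoch fit; and segments
  of 1–3 cM carry a higher proportion of detection noise in real data,
  so the fitting spectrum starts at 2 cM by default even though the
  simulator emits segments from 1 cM.
* **Epoch grid** {(1,10], (10,20], (20,40], (40,80], (80,150]}:
  geometric widening matches the resolution actually available — the
  data constrain recent epochs through long segments, which are rare,
  and old epochs through short segments, which are abundant but
  dominated by deep coalescence.
* **Smoothing** λ = 1 on squared log-steps, fixed once; it regularises
  epochs that carry few segments without visibly biasing constant-N
  recovery (< 0.01% error on noise-free spectra).
* **Optimization**: L-BFGS-B over log N with box [log 50, log 10⁷],
  5 starts around a constant method-of-moments initializer (the constant
  N matching the total count, found by uniroot); the best optimum is
  kept and reruns are deterministic given the seed.
* Confidence intervals, when requested, are bootstrap over individuals
  with the spectrum recounted (pair weights follow resample
  multiplicities) and the model refit from the fitted point.

This is explicitly **not** IBDNe: there is no within-individual
haplotype modelling, no segment gap-merging correction, and no
genome-partition bootstrap. It is a desk-scale likelihood fitter for the
same quantity, validated by parameter recovery on simulated data
(noise-free recovery within 5%, stochastic recovery within ~8% median
error at 100 diploids, bottleneck localisation to the correct epoch).
`ne_snapshot()` reads the epoch covering each canonical bin's proxy
generation, mirroring per-bin N~e~ snapshot figures.

## Community robustness

`sample_profiles()` gives each sample its vector of total cM shared with
every reference community (own contribution excluded from its own
community's entry). Published TVD analyses of this kind used
ChromoPainter copying vectors; this package is IBD-native and uses IBD
totals as the profile — a documented divergence that preserves the
contract (profiles summarise where a sample's sharing goes).

`tvd_permutation_test()` compares two groups' mean profiles by total
variation distance after dropping the two groups' own communities from
the support (mirroring the exclusion of self-copying), renormalising,
and permuting group labels: `p = (1 + #{TVD_perm ≥ TVD_obs})/(n_perm+1)`.
The test is calibrated (type-I ≈ 0.04–0.05 at α = 0.05 on panmictic
splits) and attains the minimum p on populations split 50 generations
ago. Zero-sum profiles are dropped with a warning.

`bootstrap_dendrogram()` clusters row-normalised community mean profiles
(Euclidean distance, average linkage) and attaches **ordinary bootstrap
proportions** per branch, built by resampling profile columns. This
replaces pvclust-style multiscale-bootstrap AU values deliberately: the
AU machinery is out of proportion to the validation role here, and the
contract — high support marks a robust branch — is preserved. Supports
are fractions in [0,1], the root is 1 by construction, and the tree is
exported as Newick with supports as internal node labels. With few
profile columns (few communities), column resampling is coarse and
supports are conservative; that is visible in the demo workflow and is
honest behaviour, not a defect.

## Surnames, classification, affinity

**Surnames.** `build_table()` tallies surname-origin categories per
community; `chi2_test()` is the omnibus Pearson test;
`cramers_v(adjusted = TRUE)` applies the bias correction that shrinks
φ² by its independence expectation and shrinks the effective dimensions
(the common "adjusted Cramér's V"; which exact correction a given paper
used is typically unprinted — this one is documented here).
`enrichment_cells()` reports standardized Pearson residuals with
two-sided normal p-values, Benjamini–Hochberg adjusted across cells —
the omnibus test is standard, but cell-level multiplicity handling had
to be chosen, and BH is the defensible default. Surname normalisation
(case folding, variant grouping) is the user's responsibility via their
metadata; no variant dictionary is built in.

**Classification.** `feature_matrix()` concatenates, over length bins,
each sample's total sharing with every level-2 reference community
(self-sharing excluded, so reference members can be classified without
leakage). The classifier is Gaussian naive Bayes with a variance floor
of 1e-6 and log-sum-exp posterior normalisation; the stratified 80/20
split utility is seeded. Whether a published classifier consumed genetic
features, surname features, or both is often ambiguous; this package
defaults to genetic features only, and surname-origin categories can be
appended as extra columns by the user if desired.

**Affinity PCA.** `affinity_matrix()` is the per-bin mean cM shared per
(target, reference) individual cross-pair; `pca_biplot()` centres
columns (and unit-scales them by default, so high-sharing references do
not dominate) and decomposes by SVD, fixing each component's sign so its
largest-magnitude loading is positive — a pure reproducibility
convention. Column centring (not row) makes components describe
reference-cluster contributions across communities. Bins with no
cross-sharing variance (e.g. the ≥5 cM bin against deep-split
references) are degenerate by construction and are reported as such.

## Degenerate inputs and numerical edges

* Readers reject malformed rows with the offending line number; writers
  print doubles at full precision (`%.17g`) so read∘write is the
  identity.
* `bin_segments()` is left-closed right-open; segments below the first
  edge are dropped with a count.
* An all-zero spectrum is an error ("no IBD information"), as is a
  constant affinity matrix ("no variance") and a contingency table with
  a zero marginal.
* F~ROH~ above 1 (possible because independent placements may overlap)
  is clipped with a warning.
* Leiden, all simulators, the bootstraps and permutation tests consume
  explicit integer seeds; every seeded operation is bit-reproducible.

## Problem sizes

The test suite and acceptance script run the pipeline at deliberately
desk-scale sizes chosen to keep every recovery property measurable:
25–100 diploids per population for sharing and N~e~ recovery (19,800
haplotype pairs at n = 100), 10 replicate simulations for stochastic
N~e~ error, 200 null and 100 split replicates at 199 permutations for
TVD calibration, 5000 SNPs × 200 samples for F~IS~/F~ST~ recovery, and
60-node planted hierarchies for community recovery. These sizes are the
package's study conditions; all headline recoveries hold at them.

## Known limitations

* The generator's independence assumptions (Poisson placements, no
  linkage between segments of a pair) understate positional correlation
  in real data; only count/total statistics should be trusted from it.
* The N~e~ fitter shares the generator's model, so its recovery results
  demonstrate internal consistency plus optimizer correctness; on real
  refinedIBD output its accuracy additionally depends on detection noise
  that the model does not represent — the reason the default spectrum
  starts at 2 cM.
* Clean splits only: admixture and continuous migration are not
  modelled, so cross-community sharing in simulations decays faster with
  bin length than real gene flow would produce.
* The relatedness filter's threshold and the Leiden resolutions are
  exposed defaults, not canonical values; conclusions sensitive to them
  should be checked across a range.
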