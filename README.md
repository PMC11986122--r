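# ibdscape

Demographic history from identity-by-descent (IBD) segment sharing.

`ibdscape` is an R package for population geneticists who work with
detected IBD and run-of-homozygosity (ROH) segments (refinedIBD-style
output) and want to turn them into statements about recent demography:
who clusters with whom, how population sizes changed over the last ~150
generations, which communities are isolated, and how sharing with
external reference groups shifts across time strata. It reimplements, as
a tested and reusable pipeline, the analysis style used in IBD studies of
fine-scale structure in Ireland and Britain — genetic-community detection
on IBD-sharing networks, time-stratified sharing statistics, effective
population size (N_e) inference, community-robustness testing,
surname-origin enrichment, regional-ancestry classification, and
PCA-based affinity decomposition — and pairs every stage with a
coalescent simulator so the whole pipeline can be exercised against known
ground truth.

## The model at the core

A haplotype pair coalescing `g` generations ago carries a
Poisson-distributed number of detectable IBD segments with mean

    lambda(g) = c(g) * (2 g L / 100 + K) * exp(-2 g m / 100)

where `L` is the genome's genetic length in cM, `K` the number of
chromosomes, `m` the detection threshold in cM, and segment lengths are
exponential with mean `100 / 2g` cM. The coalescence profile `c(g)`
follows a piecewise-constant N_e model: within a population,
`c(g) = (1/2N(g)) * prod_{j<g} (1 - 1/2N(j))`; across populations,
coalescence starts at the split time and proceeds in the ancestral
population. Summing over `g` gives the expected segment count per
haplotype pair in any length bin `[u, v)`:

    mu(u, v) = sum_g c(g) (2gL/100 + K) (e^(-2gu/100) - e^(-2gv/100))

This single formula is used three ways: forwards by the simulator (draw
Poisson counts and exponential lengths), backwards by the N_e fitter
(maximize the Poisson likelihood of an observed length spectrum over
per-epoch log N_e, with a smoothness penalty), and as the link between
length bins and time — short segments `[1,3)` cM proxy ~100 generations
(~3000 years), `[3,5)` ~45 generations, `>=5` cM ~15 generations.

Around it sit the field's standard statistics: Leiden modularity
clustering of the total-sharing network (edges = summed cM of segments
>= 4 cM), total-variation-distance permutation tests between community
sharing profiles, F_ROH (fraction of genome in ROH), F_IS (heterozygote
deficit), Hudson's F_ST (ratio of averages), bias-corrected Cramér's V
for surname-origin enrichment, a Gaussian naive Bayes classifier over
per-bin sharing profiles, and PCA biplots of community × reference
affinity matrices.

## Worked example

Simulate two populations of effective size 2000 that split 50
generations ago, detect communities, and compare time-stratified sharing:

```r
library(ibdscape)

genome <- default_genome()                   # 22 chromosomes, 3500 cM
model <- demography_model(
  list(A = 2000, B = 2000),
  splits = data.frame(a = "A", b = "B", generation = 50),
  ancestral = 2000)

segs <- simulate_ibd(model, c(A = 25, B = 25), genome, seed = 9)
net  <- build_network(segs, min_segment_cM = 4)
asg  <- recursive_leiden(net, levels = 1, resolutions = 1,
                         min_size = 10, seed = 1)
table(asg$level1, sub("_.*", "", asg$sample_id))
#>      A  B
#>   1 25  0
#>   2  0 25

sharing <- pairwise_sharing(segs, asg, "level1", n_boot = 0)
sharing[sharing$community_a != sharing$community_b,
        c("bin", "mean_count", "mean_total_cM")]
#>       bin mean_count mean_total_cM
#>     [1,3)   121.5280    174.997304
#>     [3,5)     3.7696     13.583155
#>   [5,Inf)     0.2480      1.428271
```

Leiden recovers the two populations exactly, and between-population
sharing collapses as segments lengthen: the two groups share plenty of
short (old, pre-split) segments but almost no long (recent) ones —
the signature of a 50-generation-old split. Fitting N_e to one
community's spectrum:

```r
ids <- paste0("A_", 1:25)
sp  <- count_spectrum(segs, ids)
fit <- fit_piecewise_ne(sp$k, sp$P, genome = genome, seed = 1)
fit$epochs[, c("g_start", "g_end", "Ne_hat")]
ne_snapshot(fit, c(1, 3))   # N_e at the ~100-generation proxy
```

## The analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
on a simulated eight-population cohort (three small-N_e "Irish-like"
communities, two larger "British-like" ones, a bottlenecked isolate, and
two continental reference clusters):

```sh
Rscript analysis/01_simulate_cohort.R      # segments, ROH, genotypes, surnames
Rscript analysis/02_network_communities.R  # network + recursive Leiden
Rscript analysis/03_time_stratified_sharing.R
Rscript analysis/04_ne_trajectories.R
Rscript analysis/05_community_validation.R # TVD tests + dendrogram
Rscript analysis/06_surname_enrichment.R
Rscript analysis/07_ancestry_classification.R
Rscript analysis/08_european_affinity.R
```

Each stage prints what it found and writes tables under `results/`. On
this cohort the detected level-1 communities are pure with respect to the
true populations; median F_ROH is ~3× higher in the small-N_e communities
(0.040 vs 0.013) while F_IS stays near 0 in all of them — the "small
N_e, not consanguinity" signature; fitted N_e snapshots track the true
sizes (e.g. ~1050–1250 for the N = 1200 populations, ~2800–4300 for the
N = 3000–3500 ones); and the surname table shows a strong
origin-by-community association (chi-squared p = 2.8e-06, bias-corrected
Cramér's V = 0.35).

The same stages can be run from one YAML config via
`run_pipeline("inst/extdata/demo_config.yaml", "outdir")`, which writes a
manifest (config hash, seeds, row counts) for reproducibility.

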