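# ecoassembly

Quantifying the ecological processes that assemble microbial communities
along environmental gradients — and validating every inference step on
synthetic communities whose assembly process is known.

The package targets the standard analysis stack of 16S amplicon surveys
(free-living vs particle-attached estuarine bacterioplankton is the
motivating design): an ASV count table, a rooted phylogeny of the ASVs,
and per-sample environmental metadata go in; per-pair assembly processes,
co-occurrence (cohesion) metrics, and constrained-ordination variance
structure come out.

## What it computes

**Pairwise assembly processes** (the Stegen null-model framework). For
samples *k*, *m* with relative abundances *f* and patristic distances *d*:

    βMNTD(k,m) = ½ [ Σ_{i∈k} f_ik · min_{j∈m} d(i,j) + Σ_{j∈m} f_jm · min_{i∈k} d(j,i) ]

βNTI is the z-score of the observed βMNTD against a 999-draw tip-shuffle
null (taxon names and abundances move together across tips; topology and
branch lengths fixed). βNTI < −2 → homogeneous selection, βNTI > 2 →
variable selection. Pairs within ±2 get the Raup–Crick score on
Bray–Curtis, RC ∈ [−1, 1], from a null that preserves each sample's
richness and read total while drawing members by regional occupancy and
reads by regional abundance: RC > 0.95 → dispersal limitation,
RC < −0.95 → homogenizing dispersal, otherwise undominated. The βMNTD
null loop is C++.

**Cohesion** (Herren–McMahon): pairwise Pearson correlations of relative
abundances, corrected by a 200-iteration taxa-shuffle expectation; per
taxon, connectedness = mean of the strictly positive (negative) corrected
correlations; per sample, cohesion = abundance-weighted connectedness sum,
in [0, 1] and [−1, 0].

**Diversity and ordination**: richness, Shannon (nats), rooted Faith's PD;
Bray–Curtis; PCoA with the Cailliez correction; PERMANOVA (sequential SS)
and dispersion tests; distance-based RDA with z-scored predictors, VIF
pruning (< 10), Ezekiel-adjusted R², and commonality-analysis variance
partitioning over 2–4 predictor groups whose cells sum exactly to the
full-model adjusted R².

**Synthetic data**: Yule trees, Brownian niche traits with optional
clade-level conservatism, selection/neutral/dispersal community
generators, planted co-occurrence structure, and a full 9-station ×
5-date × FL/PA synthetic estuarine survey with a salinity-following
nutrient field — the ground truth all recovery tests run against.

## Worked example

```r
library(ecoassembly)

# a community set assembled under homogeneous selection (known truth)
sc  <- simulate_assembly_scenario("homogeneous_selection",
                                  n_taxa = 80, n_samples = 8,
                                  depth = 1500, seed = 1)
res <- assembly_analysis(sc$counts, sc$tree, n_null = 199, seed = 2)
summarize_processes(res)
#> # A tibble: 5 × 4
#>   group process                    n fraction
#>   <chr> <fct>                  <int>    <dbl>
#> 1 all   variable_selection         0    0
#> 2 all   homogeneous_selection     16    0.571
#> 3 all   homogenizing_dispersal     0    0
#> 4 all   dispersal_limitation       0    0
#> 5 all   undominated               12    0.429
```

The dominant label is homogeneous selection — the process the generator
actually used; the remainder is classified as drift, which is expected at
this miniature size (80 taxa, 8 samples): βNTI z-scores sharpen with pool
size, and at the study scale used in the tests (200 taxa, 20 samples,
999 null draws) recovery exceeds 90% of pairs. The per-pair detail
(observed βMNTD, null mean/SD, βNTI, RC, label) is in `res` itself.

The full survey pipeline runs from one configuration object and is
deterministic given its seed:

```r
cfg <- analysis_config(simulate = scenario_config(), seed = 1)
run <- run_pipeline(cfg, output_dir = "run1")   # writes TSVs + manifest.json
tidy(run$ordination$permanova_bc)               # station/date/fraction R²
glance(run$constrained$FL$fit)                  # dbRDA adjusted R²
run$assembly$summary                            # process fractions per group
```

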