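---
title: "Inferring community assembly processes from count tables and phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes from count tables and phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The scientific question

Microbial communities sampled along an environmental gradient — here the
motivating system is an estuarine salinity gradient with free-living (FL)
and particle-attached (PA) bacterial fractions — are shaped by a mixture of
deterministic selection (the environment filters taxa by their niches) and
stochastic processes (drift, dispersal). `ecoassembly` implements the
phylogenetic null-model framework that partitions these influences per
sample pair, plus the co-occurrence (cohesion) metrics and the constrained
ordination layer that link community structure to measured abiotic
variables.

## The pairwise assembly model

For samples $k$ and $m$ with within-sample relative abundances $f$, the
abundance-weighted beta mean nearest taxon distance is

$$\beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\sum_{i\in k} f_{ik}\,\min_{j\in m} d(i,j)
 + \sum_{j\in m} f_{jm}\,\min_{i\in k} d(j,i)\Big],$$

with $d$ the patristic distance on the rooted phylogeny; a taxon present in
both samples contributes 0. The null model shuffles taxon identities (name
and abundance together) across the tips, keeping topology and branch
lengths fixed; one shared permutation per draw serves all pairs. The beta
nearest taxon index is the z-score
$\beta\mathrm{NTI} = (\mathrm{obs} - \mu_0)/\sigma_0$ over (by convention)
999 draws. $\beta\mathrm{NTI} < -2$ is read as homogeneous selection,
$> 2$ as variable selection.

Pairs inside the $\pm 2$ band are passed to the Raup–Crick score on
Bray–Curtis: null communities preserve each sample's richness and read
total, drawing members with probability proportional to regional occupancy
and filling reads by regional relative abundance; the observed Bray–Curtis
is ranked in the null distribution (ties half-weighted) and rescaled to
$[-1,1]$. Beyond $+0.95$/$-0.95$ the pair is labelled dispersal
limitation / homogenizing dispersal, otherwise undominated. All threshold
comparisons are strict; values exactly at a threshold fall through to the
next rule. A pair whose null distribution has zero spread (possible on
star-like trees or identical samples) is flagged degenerate and excluded
from process fractions rather than crashing a division.

```{r assembly-example}
sc <- simulate_assembly_scenario("homogeneous_selection", n_taxa = 80,
                                 n_samples = 8, depth = 1500, seed = 1)
res <- assembly_analysis(sc$counts, sc$tree, n_null = 199, seed = 2)
summarize_processes(res)
```

## What the synthetic generators emulate

Every inference stage is validated by parameter recovery on generated data,
so the generators are first-class, tested code.

* **Phylogeny** — pure-birth (Yule) trees with exponential waiting times.
* **Niche traits** — Brownian motion along branches
  (`evolve_niche_traits()`). On pure-birth trees most divergence happens
  close to the tips, so plain tip-level Brownian traits carry almost no
  clade-level signal — and a tip-shuffle null can only see selection when
  community membership is phylogenetically clustered. `conserve_niches()`
  therefore freezes trait evolution once a chosen number of lineages
  exists (default 12 in the recovery scenarios), giving genus-like
  subclades of functionally redundant taxa. This mirrors the niche
  conservatism that the interpretation of betaNTI assumes in real 16S
  data.
* **Selection** — sampling weights combine log-normal metacommunity
  abundances with a Gaussian niche filter
  $\exp(-(t_i - E)^2 / 2\sigma_f^2)$. A `retention` probability (0.5 in
  the recovery scenarios, 1 by default) models stochastic arrival: each
  taxon reaches each sample independently with that probability, so
  equally adapted close relatives replace each other across samples —
  exactly the turnover signature homogeneous selection leaves in real
  communities. Without it, samples under a common optimum are
  near-identical multinomial draws and carry no detectable signal.
* **Scenario anchors** — the homogeneous-selection scenario anchors the
  optimum on a mid-size conserved clade (15–45 tips out of 200) chosen for
  the largest trait-space gap to its nearest neighbouring clade, with the
  filter width scaled to that gap ($\sigma_f = \min(0.5, \mathrm{gap}/5)$
  PSU) so exactly one niche is selected regardless of the tree
  realization; variable selection uses the two most trait-distant sizeable
  clades as two sample blocks. These choices were fixed at design time and
  verified across independent tree seeds.
* **Co-occurrence** — `plant_cooccurrence()` couples taxon groups to a
  per-sample latent factor $z$: abundances are scaled by
  $e^{\pm\lambda z}$ and re-drawn at the original depth, creating positive
  within-group and negative cross-group correlations for cohesion to
  detect.
* **The estuarine survey** — `simulate_estuary_dataset()` emulates a
  9-station salinity gradient (0–34 PSU, two freshwater stations, one
  marine reference) sampled on 5 dates (two of them summer) in both FL and
  PA fractions: 90 samples. Dissolved inorganic nitrogen and silicate
  follow the conservative dilution line with salinity (Spearman
  correlations near −0.95 at default noise); phosphate and suspended
  particulate matter peak in the mid-estuary maximum turbidity zone;
  temperature carries a seasonal signal whose river-to-sea gradient flips
  sign between winter and summer. The PA fraction re-weights a designated
  "particle specialist" clade by $e^{\mathrm{skew}}$, making FL–PA
  dissimilarity a single monotone knob; a handful of tips are labelled as
  chloroplast / mitochondrial / archaeal / eukaryotic lineages so the
  taxonomy filter has real work to do.

What the generators deliberately do **not** emulate: sequence-level error,
chimeras, variable library sizes, hydrodynamics, or any quantitative FL–PA
exchange process. Passing recovery tests therefore demonstrates that the
inference machinery detects the processes it claims to detect under its
own assumptions — not that those assumptions hold in any particular real
data set.

## Cohesion

Pairwise Pearson correlations of relative abundances are corrected by the
expected correlation under a taxa shuffle (each taxon's vector permuted
across samples; 200 iterations by default; shuffles are applied in sorted
taxon order so results do not depend on column order). Per taxon,
connectedness is the mean of the strictly positive (respectively strictly
negative) corrected correlations; per sample, cohesion is the
relative-abundance-weighted sum of connectedness. The conventional
prefilters are applied first: taxa with fewer than 150 reads overall are
dropped (strict less-than; 150 exactly is kept), then taxa present in
fewer than 10% of samples.

A limitation worth knowing: the per-pair null correction removes the
*bias* that compositionality and skewed abundance distributions induce,
not the *sampling noise* of a correlation estimated from $n$ samples. On
fully independent taxa the corrected correlations are noise with standard
deviation $\approx 1/\sqrt{n-1}$, so the mean of their positive part — and
hence cohesion — has a floor of about $\sqrt{2/\pi}/\sqrt{n-1}$ ($\approx
0.15$ at $n = 30$). Cohesion values should be compared between samples of
the same design, not read as absolute zeros.

## Ordination and variance partitioning

Principal coordinates use Gower double-centering; the Cailliez constant
(found via the standard $2n \times 2n$ companion eigenproblem) is added to
off-diagonal dissimilarities when negative eigenvalues appear, and is
reported in the result. PERMANOVA delegates to `vegan::adonis2()` with
sequential (Type-I) sums of squares in the caller's term order and
unrestricted row permutation; dispersion homogeneity uses
`vegan::betadisper()` on the Cailliez-corrected matrix with group
centroids. Distance-based RDA is `vegan::capscale()` with the Cailliez
constant, keeping **all** positive principal-coordinate axes as the
response so total inertia is preserved; explained variance is adjusted by
the Ezekiel formula $1-(1-R^2)(n-1)/(n-m-1)$. Predictors are z-scored and
pruned beforehand by iterative variance-inflation-factor removal
(threshold 10; infinite VIFs go first). Variance partitioning fits the
dbRDA for every non-empty subset of 2–4 predictor groups and solves the
commonality (inclusion–exclusion) linear system exactly, so the cells
always sum to the full-model adjusted $R^2$; negative cells are retained
in machine output and left to the caller to suppress in display.

```{r ordination-example}
sim <- simulate_estuary_dataset(scenario_config(n_taxa = 80, depth = 1200),
                                seed = 3)
rel <- to_relative_abundance(sim$counts)
bc <- bray_curtis(rel)
fit <- permanova(bc, sim$metadata, c("station", "date", "fraction"),
                 n_perm = 199, seed = 4)
tidy(fit)
```

## Numerical choices and degenerate inputs

* Permutation p-values always use $(1 + \#\{F^\ast \ge F\})/(1 + n_\mathrm{perm})$,
  so no p-value is ever 0.
* Rarefaction is a multivariate hypergeometric draw (without replacement);
  samples under the target depth are dropped with a warning naming them,
  never padded.
* "Fewer than 150 reads" is strict: taxa at exactly the threshold stay.
* Constant abundance vectors have undefined Pearson correlations; they are
  set to 0 with a warning.
* Zero-length branches are allowed, negative ones rejected; a missing root
  edge length is treated as 0.
* Every function that consumes randomness takes an explicit `seed` and
  leaves the caller's RNG untouched; the pipeline derives per-stage (and
  per-pair) substreams from one master seed, so adding a stage never
  perturbs another stage's stream and any subset of pairs reproduces the
  full run.

## Problem sizes used in the validation suite

The recovery studies run at 200 taxa, 20 samples and 5,000 reads per
sample with 999 null draws — sizes chosen so that the full suite completes
in minutes on a single CPU while each scenario still contains enough
pairwise information for stable z-scores. The survey-level checks use the
90-sample synthetic estuary at the same taxon count. The package applies
identically to larger tables; the betaMNTD null loop is implemented in
C++ and scales as (taxa × richness + pairs × richness) per draw.

## Known limitations

* The cohesion noise floor described above.
* Process classification inherits the framework's assumptions: niche
  conservatism on the tree, a meaningful regional pool, and sequencing
  depth high enough that membership is not dominated by detection noise.
* The FL–PA skew is a phenomenological knob, not a mechanistic exchange
  model; only its monotone effect on dissimilarity is validated.
* betaNTI magnitudes depend on pool size; with small taxon pools the
  \(|2|\) threshold is conservative.
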