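---
title: "Models and methods: null-model assembly inference on cross-kingdom soil communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilassembly)
```

## What the package computes

`soilassembly` is a pipeline for asking how soil bacterial communities are
assembled — how much of their spatial turnover is driven by deterministic
selection along environmental gradients versus stochastic drift and
dispersal — and how soil fungi, through cross-kingdom associations,
modulate that balance. It covers five analysis stages plus a synthetic-data
generator that plants known assembly regimes so each stage can be validated
against ground truth.

### Phylogenetic null-model inference (βMNTD / βNTI)

For two communities $k$ and $m$ with within-sample relative abundances
$f$, the abundance-weighted beta mean nearest taxon distance is

$$\beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\sum_{i \in k} f_{ik}
\min_{j \in m} d_{ij} + \sum_{j \in m} f_{jm} \min_{i \in k} d_{ij}\Big],$$

where $d$ is the cophenetic (patristic) distance on the bacterial
phylogeny and minima run over taxa present in the other sample (a shared
taxon contributes distance 0). The beta nearest taxon index is the z-score
of the observed value against a null distribution obtained by shuffling
taxon labels across the tips of the phylogeny with the communities held
fixed:

$$\beta\mathrm{NTI}(k,m) = \frac{\beta\mathrm{MNTD}_{obs} -
\overline{\beta\mathrm{MNTD}}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}.$$

Pairs with $\beta$NTI $< -2$ are classified as homogeneous selection (HS:
less phylogenetic turnover than chance), $> 2$ as variable selection (VS:
more turnover than chance), and $|\beta\mathrm{NTI}| \le 2$ as stochastic
(Sto). The inequalities are strict for the two selection classes and the
boundary belongs to the stochastic class.

Two null-model choices deserve emphasis:

* **The shuffle runs over all tips of the supplied tree**, not only the
  taxa observed in the count table. When the table covers every tip the
  two conventions coincide; when it does not, restricting the null to the
  observed taxa conditions it on the very pool that selection produced.
  If all samples are filtered into one clade, the observed pool *is* that
  clade, and a pruned-pool null can no longer detect homogeneous
  selection at all. Passing a tree that represents the regional
  metacommunity makes the null a genuine "random phylogenetic structure"
  reference.
* **βMNTD is abundance-weighted** on relative abundances from the
  (rarefied) table; an unweighted variant (equal weights over present
  taxa) is available via `weighted = FALSE`. Note that the unweighted
  definition used here is the half-sum of the two per-sample means; some
  implementations instead average the pooled list of nearest-taxon
  distances, which differs when richness differs between the samples.

The null is recomputed pair-wise with running moments, so `n_null = 999`
(the production default) costs seconds, not minutes, at a few hundred
taxa. Tests use 199 draws: βNTI is a z-score, so null-sample noise
degrades precision gracefully rather than biasing it. Pairs whose null
spread is exactly zero (e.g. a star phylogeny, where every shuffle is
isometric) are reported as `NaN` with a warning rather than silently
dropped.

### Assembly fractions along a fungal-richness gradient

`richness_group_analysis()` ranks samples by fungal richness (ties broken
by input order), cuts them into contiguous near-equal-size groups, and
computes the HS/VS/Sto fractions over the *within-group* βNTI pairs. Each
fraction is then fit with a second-order polynomial in group mean
richness, and the reported trend sign is the sign of the fitted first
derivative averaged over the observed richness range — a robust scalar
summary of "does this process grow or shrink with fungal richness". Group
counts of 14 and 21 are exposed as a parameter because the grouping
resolution is a presentation choice, not a model property; equal-size
rank groups were chosen over equal-width bins because they keep the
per-group pair counts balanced.

### Cross-kingdom co-occurrence networks

Edges connect taxon pairs (within and across kingdoms) whose Spearman
rank correlation across samples satisfies $|\rho| > 0.6$ with two-sided
$p < 0.001$ from the t approximation on average ranks, with no
multiplicity correction — the conventional thresholding for comparability
across amplicon studies. Correlations are computed on rarefied counts;
because ranks are taken within a taxon across a shared sample set,
any per-sample monotone rescaling (counts versus relative abundances)
leaves the edge set unchanged, and the tests assert this invariance.

Per-sample *sub-network features* are computed on the subgraph induced by
the taxa detected in that sample: average degree AD $= 2E/N$, the
proportion of negative edges (Neg), and the proportion of
bacterium–fungus edges (Int, counted against all edges of the
subnetwork). Samples whose subnetwork has no edges get all features 0 and
a flag column instead of being dropped, so downstream regressions keep
their sample alignment and can exclude flagged rows explicitly.

*Niche preference* of a taxon for an environmental variable is the mean
of that variable over the samples where the taxon is detected, weighted
by the taxon's relative abundance in those samples — a simple
abundance-weighted centroid of its realized niche.

### Distance decay and driver attribution

Distance–decay relationships are ordinary least-squares fits of pairwise
community similarity ($1 -$ Bray–Curtis) on great-circle distance
(haversine, Earth radius 6371 km), per habitat. Because pairwise points
are not independent, significance comes from Mantel-style permutations of
the distance matrix, not the parametric t-test; a `log10_distance` switch
covers the alternative x-axis convention. The Mantel test itself uses
Pearson correlation of upper triangles, one-tailed positive by default,
with the add-one permutation estimator $p = (1 + \#\{r^* \ge r\})/(1 +
n_{perm})$; the partial variant residualizes both triangles on the
conditioning matrix and permutes the residual matrix of the second
(method of residuals).

LMG variance decomposition assigns predictor $j$ the average increase in
$R^2$ when it enters the regression, over all orderings of the
predictors, computed by exact subset enumeration (feasible to 12
predictors; a seeded random-ordering estimator with declared Monte-Carlo
error handles wider sets). Shares are non-negative, sum exactly to the
full-model $R^2$, and reduce to marginal $r^2$ in orthogonal designs —
all asserted in tests. Forward selection on the Bray–Curtis matrix embeds
$\sqrt{BC}$ by principal coordinates (the square root makes the
dissimilarity Euclidean-embeddable, avoiding negative eigenvalues),
greedily adds the standardized driver with the largest gain in explained
variance, and admits it while its permutation p-value stays at or below
α. Random-forest importance significance follows the
response-permutation scheme: the forest is refit on shuffled responses
and each observed %IncMSE is compared against its own null distribution.

## The synthetic-data generator

The generator is first-class, tested code: it is the ground truth against
which the whole inference chain is validated. The field study it emulates
is observational, so every regime parameterization here is a constructed
stand-in, not an estimate of any real soil process.

One environmental axis (standardized aridity, AI) does the mechanical
work; the other metadata columns (pH, moisture, nutrients, MAT) are
correlated decorations with field-realistic signs, because the assembly
analyses key on scalar drivers. AI increases eastward across a
36–41° N / 94–104° E box with noise, so geographic and environmental
distances are correlated — which is exactly what a distance-decay
relationship needs. Habitats are AI rank quintiles (wetland → desert).

Bacterial communities follow a niche-filtering model on a pure-birth
(Yule) phylogeny:

* **Clade-conserved optima.** Niche optima evolve by Brownian motion on a
  root-concentrated branch-length transform of the tree (Pagel delta,
  default 0.05). Plain BM on a Yule tree yields a trait–phylogeny
  distance correlation near 0.2 — too weak for selection to leave any
  detectable phylogenetic footprint at a 100-taxon pool. Concentrating
  trait change near the root makes optima approximately constant within
  major clades, raising that correlation to ~0.9.
* **Truncated Gaussian niche.** Expected abundance of taxon $i$ in sample
  $s$ is proportional to $b_i \exp(-w_s (e_s - o_i)^2 / 2\sigma^2)$ with
  lognormal metacommunity weights $b$ (sdlog 0.5), and the kernel is set
  to zero below half height (phasing in with the selection weight
  $w_s$): outside its niche window a taxon cannot establish. Without the
  truncation, the Gaussian tail keeps a halo of phylogenetically
  scattered taxa in every sample, which bridges nearest-taxon distances
  and washes out both HS and VS signals.
* **Occupancy turnover.** Each sample retains each available taxon with
  a Bernoulli probability (defaults 0.55 under homogeneous selection,
  0.80 along the gradient, 0.65 under neutrality), making every
  community an independent random subset of its guild. This ecological
  drift in membership is what gives sample pairs the compositional
  turnover that null-model inference measures; without it, identically
  filtered samples are near-identical and βNTI has nothing to contrast.
* **Propagule rain.** A few taxa from outside the resident community
  (expected read fraction `immigration = 0.003`) arrive at near-singleton
  abundance per sample. This keeps the regional pool observable — the
  tip-shuffle null needs the unselected clades on record — without
  letting scattered immigrants dilute the residents' phylogenetic
  signal.
* **Regime mechanics.** `neutral` drops the kernel entirely;
  `homogeneous_filtering` filters every sample at one shared
  environmental value; `variable_filtering` maps the aridity gradient
  onto the quantiles of the optima distribution, so the gradient sweeps
  the whole niche space and every sample has a viable guild;
  `richness_coupled` scales the selection weight $w_s$ linearly with the
  sample's rank in fungal richness, from no selection to full homogeneous
  selection — the planted version of a fungal-diversity gradient
  modulating selection on bacteria.
* **Planted guilds must exist to be planted.** For the shared-value
  regimes the generator places the environmental value where the niche
  window captures the most phylogenetically coherent guild (scored by
  the expected minimum distance from a guild member to a random
  occupancy-sized subset of the guild, relative to the same quantity
  over random tips), and redraws the optima (bounded, seeded, at most 8
  tries) until that ratio falls below 0.40. Brownian motion converges:
  an arbitrary trait window can select a phylogenetically scattered set,
  in which case no method could — or should — call the regime
  deterministic. The redraw guarantees the regime is actually present in
  the realized tree/optima pair.

Fungal communities implement the richness gradient by truncation: at
treatment level $j$ only the first `richness_levels[j]` taxa of the
lognormal pool can occur. This mirrors a fungicide-dose experiment in its
*tested variable* — fungal richness — without modelling chemistry.
Sequencing depth is Poisson per sample (default mean 500) and counts are
multinomial, so rarefaction has realistic work to do.

What the generator does **not** emulate: compositional (closed-sum)
correlation artefacts, sequencing error and chimeras, taxonomy,
spatially-explicit dispersal kernels, temporal dynamics, and any
bacteria→fungi feedback. Passing tests therefore demonstrate that the
*inference machinery* recovers planted truth under this model family —
not that real soils behave like the model.

## Numerical choices and edge cases

* Shannon diversity uses natural logarithms (nats).
* Rarefaction is one seeded draw without replacement
  (multivariate-hypergeometric); samples below depth are dropped with a
  warning naming them. Taxa left with zero total count are removed, since
  count tables never carry all-zero columns.
* Presence means count > 0 after rarefaction, everywhere.
* The prevalence filter and the dominant-taxa occupancy rule use strict
  inequalities ("more than 10%", "more than 50%").
* Spearman p-values use the t approximation with average ranks; exact
  ±1 correlations get p = 0.
* All permutation p-values use the add-one estimator, so the smallest
  attainable p is $1/(n_{perm}+1)$; every stochastic operation takes an
  explicit seed and is reproducible.
* The Mantel triangle excludes non-finite pairs (NaN βNTI entries) from
  both the observed statistic and every permutation.
* Degenerate inputs error with classed conditions (`degenerate_input`,
  `collinearity`, `label_mismatch`, ...) rather than returning NA.
* A partial Mantel whose conditioning matrix explains either input
  (residual variance below 1e-12 of the original) returns $r = 0$,
  $p = 1$.

## Problem sizes

The validation suite runs at desk scale, chosen so planted effects are
comfortably detectable: 20 samples × 100 taxa with 199 null draws for
regime recovery; 84 samples for the richness-gradient trends (14 and 21
groups); 21 samples (210 pairs) for null calibration; 200 replicates at
n = 15 for Mantel type-I calibration; 100 samples × 100 taxa for network
recovery. Production analyses can raise `n_null` to 999 and scale sample
and taxon counts freely; the βMNTD engine is vectorized over sample pairs
(one matrix product per null draw), so cost grows roughly linearly in
`n_null` and quadratically in samples.

## Known limitations

* βNTI power at a 100-taxon pool is intrinsically modest; homogeneous
  selection in particular sits near the |2| threshold, and a minority of
  random trees do not admit a detectable clade guild even after redraws.
  Larger pools separate the regimes much more cleanly.
* The three-way HS/VS/Sto split is implemented without the further
  partition of the stochastic class (dispersal limitation versus drift)
  that Raup–Crick-type taxonomic nulls provide.
* LMG enumeration is exact only to 12 predictors; beyond that the
  random-ordering estimator introduces Monte-Carlo error of order
  $1/\sqrt{n_{orderings}}$.
* The co-occurrence network is threshold-based Spearman; it inherits the
  known compositionality caveats of correlation networks on relative
  abundance data.
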