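---
title: "Interdomain plant-soil bacteria networks with idenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interdomain plant-soil bacteria networks with idenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aboveground plant communities and belowground soil bacterial communities
are sampled with entirely different instruments — stem counts in vegetation
plots on one side, 16S rRNA amplicon sequencing of pooled soil cores on the
other — yet they are ecologically coupled. `idenet` infers and analyses
*interdomain ecological networks* (IDENs): bipartite networks whose two
node sets are plant species and bacterial OTUs, with an edge wherever the
two covary across plots more strongly than a compositional null allows.

The pipeline is: (1) read and validate the plant survey, OTU table and
taxonomy; (2) rarefy the OTU table to a common depth; (3) stack both
domains into one composition per plot; (4) estimate SparCC correlations
with permutation pseudo p-values; (5) threshold into a bipartite incidence
network; (6) compute a topology panel; (7) test it against degree-preserving
null networks; (8) detect modules by simulated annealing and classify node
roles; (9) compare several sites.

## Why SparCC

Sequencing counts are compositional: each sample's reads are an arbitrary
share of an unobserved total, so naive correlations between relative
abundances are biased (negatively, on average). SparCC works from the
log-ratio variation matrix `t_ij = Var(log(x_i/x_j))`, which is invariant
to per-sample rescaling, and approximates the latent *basis* correlations
under a sparsity assumption by solving
`t_i. = (D - 2) w_i + sum_j w_j` for the basis variances `w` and setting
`rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clipped to `[-1, 1]`.
Strongly correlated pairs violate the sparsity assumption, so the single
strongest pair above a threshold (default |rho| > 0.1) is removed from the
system and the solve repeated, up to 10 rounds. Sampling noise is averaged
over 20 Dirichlet draws of the per-sample fractions (posterior with
pseudocount 1), combined by an element-wise median for robustness to
occasional degenerate draws.

Statistical significance uses a permutation pseudo p-value: each feature
row is independently permuted across plots and the full estimator re-run;
`p_ij = (1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`. The add-one
correction keeps the minimum attainable p at `1/(n_perm + 1)` and avoids
p = 0 artifacts. Permutation (rather than sample bootstrap) was chosen
because it preserves each feature's marginal count distribution exactly
while destroying association, which is the null actually being tested; the
choice is exposed in the documentation rather than as a switch because the
two resampling schemes answer different questions.

Both domains are stacked into *one* composition per plot before SparCC.
Plant stem counts are tiny relative to 20,000 sequencing reads, but the
variation matrix only uses within-feature variation across plots, so the
scale difference is immaterial. Whether plant abundances should first be
made relative within plots is genuinely open; the default is raw stem
counts, with `plant_transform = "relative"` available in
`stack_domains()`.

## Thresholding and the network unit

Edges keep pairs with `|rho| >= 0.3` and `p < 0.05`, interdomain pairs
only; intradomain (plant-plant, OTU-OTU) correlations are computed as part
of the joint composition but never become edges. Species without a
surviving edge are dropped, so the reported "number of microbes" counts
only network-associated OTUs — that is the unit all topology metrics and
the cross-site Venn arithmetic operate on. The sign of rho is kept as an
edge attribute; thresholding uses |rho| because positive-only filtering is
an additional assumption we do not impose.

## The topology panel

For a network with `P` plants, `M` microbes and `L` links:

* connectance `L/(P*M)`, web asymmetry `(P - M)/(P + M)`, links per
  species `L/(P + M)` — closed forms, reported to 3 decimals;
* clustering: the Watts-Strogatz local coefficient averaged over the nodes
  of both one-mode projections (bipartite clustering is ambiguous; the
  projection variant is labeled as such and alternatives are pluggable);
* nestedness: NODF on the 0-100 scale (binary) and weighted NODF on 0-1,
  both following the overlap-and-decreasing-fill definition (ties in fill
  contribute zero); our implementation is tested cell-for-cell against an
  independent reference estimator;
* specialization: Kullback-Leibler `d'` per node with
  `d' = d / ln(A../A_i.)` (0 = partner use proportional to availability,
  1 = exclusive use of an otherwise unused partner). The exact
  integer-constrained minimum of `d` requires a heuristic search; we use 0,
  the continuous lower bound, which both limiting cases above satisfy.
  Specialization asymmetry is `(<d'>_otus - <d'>_plants) /
  (<d'>_otus + <d'>_plants)` — positive when the species-rich microbial
  level is the more specialized one — with the absolute value also
  reported;
* checkerboard C-scores per level: mean of
  `(r_i - S_ij)(r_j - S_ij)` over species pairs.

## Null model and significance

Null networks preserve both degree sequences exactly (fixed-fixed):
checkerboard `2x2` submatrices `[[1,0],[0,1]]` are flipped, 10·L accepted
swaps after a 1,000-attempt burn-in. One hundred rewired networks form the
null sample for each metric; significance is a one-sample t test of the
null sample against the observed value (`df = n - 1`, two-sided), with a
z-score reported alongside because t statistics on correlated rewires are
anti-conservative. Metrics fixed by the margins (connectance, links per
species) come out degenerate under this null and are flagged rather than
tested. Fixed-row/equiprobable alternatives can be supplied via the
`metrics`/rewire arguments.

## Modules and roles

Module detection maximizes Barber's bipartite modularity
`Q_B = (1/L) sum_ij (A_ij - k_i d_j / L) delta(g_i, g_j)` by simulated
annealing in the Guimerà–Amaral style: start from singleton modules;
per temperature stage propose `c·(P+M)` single-node reassignments plus a
few whole-module merges and random bisection splits; accept improvements
always and deteriorations with probability `exp(dQ/T)`; cool geometrically
(`T0 = 1`, factor 0.995 per stage) until `T < 1e-5` or three stages pass
with no acceptance. The best-ever partition is returned, first-found on
ties, fully reproducible under the seed. The annealer is implemented in
C++ (the only hot loop in the package); the returned Q is recomputed in R
from the definition as a cross-check.

Node roles use the within-module degree z-score `Zi` and participation
coefficient `Pi = 1 - sum_t (k_it/k_i)^2`, with the standard (2.5, 0.62)
thresholds: network hub (both exceeded), module hub (only Zi), connector
(only Pi), peripheral (neither). `Zi` is standardized within the node's
own module *and* bipartite level, so a module's lone plant is not scored
against dozens of OTUs; pooling both levels is available via
`level_normalization = FALSE`.

## Cross-site comparison

Venn regions are computed over the *network-associated* OTU sets of 2-4
sites. Percentage conventions: a site's unique percentage divides its
exclusive count by its own set size; a pairwise shared percentage divides
the intersection by the union — the only convention that reproduces the
published cross-site values from their set sizes and intersections.

## The synthetic generator

`simulate_iden()` emulates one site of the study design: 17 plots by
default, 8 plant species in 4 modules, 150 OTUs at 20,000 reads per plot.
Plants get independent log-normal latent abundances (log-scale SD 1 around
20 stems), observed as Poisson counts. 60% of OTUs are planted: each picks
one partner plant and multiplies its own log-normal baseline by
`effect_size^z`, `z` the partner's standardized log abundance, so an
effect size of 3 triples an OTU's expected share per SD of its partner.
One hub plant takes ~30% of all planted OTUs (at least 3x the median
partner count), mirroring the single dominant-degree tree observed in the
study. OTU counts are drawn multinomially per plot, making the table
exactly compositional. What the generator does *not* emulate: read-level
sequencing error, phylogenetic correlation among OTUs, spatial
autocorrelation among plots, and plant-plant interactions — so passing
recovery tests demonstrates correctness of the inference machinery on
compositional count data, not robustness to every property of field data.

`shuffle_nulls()` permutes each OTU row independently across plots: a
negative control that keeps every row's count multiset while destroying
all interdomain association.

## Numerical choices and degenerate inputs

* Rarefaction is a single seeded draw without replacement (not a mean over
  repeated draws); under-depth samples are dropped with a warning.
* A prevalence filter (default: present in at least half the plots)
  stabilizes SparCC at n = 17; it is configurable and can be disabled.
* Non-positive basis variances (rare, degenerate draws) are replaced by
  the smallest positive one with a warning; pair exclusion never
  disconnects a feature from the solve entirely.
* NODF of a single-row/column matrix is defined as 0 with a warning;
  C-score requires two species at the level.
* The master seed fans out additively to stage seeds (simulate +1, rarefy
  +2, SparCC +3, nulls +4, annealing +5), so any stage re-run in isolation
  reproduces its in-pipeline result.

## Problem sizes used in validation

The packaged tests exercise the estimator at the study's plot count
(n = 17) for type-I control and at n = 100 plots for planted-edge
recovery (the regime where |rho| = 0.3 is a ~3 SE event under the null),
with the default 100 permutations. Module recovery uses planted 4-block
networks of 8 plants and 40 OTUs. These sizes were chosen as the smallest
at which the statistical claims are sharp; all scale linearly upward via
the configuration objects.

## Worked example

```{r, eval = FALSE}
library(idenet)

run <- run_site(run_config(
  site = "demo",
  synthetic = synthetic_config(n_plots = 17, n_otus = 150, seed = 1),
  out_dir = "demo_out", seed = 1))

run$topology          # the metric panel
run$nulls             # null-model significance per metric
run$partition         # modules and Barber Q
head(run$roles)       # Zi, Pi and role per node
```

## Known limitations

* The t test treats 100 rewires as independent draws; use the reported
  z-scores when in doubt.
* Simulated annealing is stochastic search: Q is a lower bound on the
  optimum. On separable instances the tests require exact recovery, but
  hard instances may need slower cooling (`anneal_control()`).
* Nestedness and clustering have several variants in the literature; the
  implemented ones are labeled (NODF; one-mode projection clustering), and
  values from other estimators are not directly comparable.
* SparCC assumes most pairs are uncorrelated; very dense true networks
  violate this and bias correlations downward.
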