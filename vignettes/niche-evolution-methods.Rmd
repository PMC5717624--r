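---
title: "Methods: bioclimatic niche evolution with multi-regime BM/OU models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioclimatic niche evolution with multi-regime BM/OU models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the overall design

phyloniche implements a comparative analysis of bioclimatic-niche evolution
for an island plant radiation and its pollinators. The motivating system is
a clade of Antillean plants pollinated by hummingbirds, bats, or both, with
species largely confined to single islands of the Greater Antilles. Two
macroevolutionary hypotheses are confronted: that the *realized* climatic
niche of a plant species is shaped by its pollination mode (because the
plant can only persist where its pollinators occur), and that it is shaped
by island membership (because each island offers its own envelope of
available climates). The pipeline answers in two complementary ways:

1. **Pattern in the present**: pairwise niche overlap between species,
   explained by shared pollination mode and shared island in linear models
   compared by AIC.
2. **Process through time**: six models of trait evolution on the phylogeny
   — Brownian motion with one rate (BM1), with one rate per pollination
   mode (BM3), per island (BM4); Ornstein–Uhlenbeck with one optimum (OU1),
   one optimum per pollination mode (OU3), per island (OU4) — compared by
   small-sample Akaike weights, with occurrence and phylogenetic
   uncertainty propagated by jackknifing presence records and resampling
   trees.

A single-regime OU winning over all multi-regime models is the signature of
phylogenetic niche conservatism: species track a common climatic optimum
regardless of pollinator or island.

# The environmental space

The background is a raster of pixels (the study grain is a 5-arc-minute
grid, 3458 land pixels over the Antilles) carrying altitude plus 19
bioclimatic variables. `fit_env_space()` runs a PCA on the **correlation**
matrix — every variable standardized to mean 0, sd 1, so each gets equal
weight regardless of units — and keeps the first two components as the
niche space. Two numerical choices are fixed here:

* **Sign convention.** The sign of an eigenvector is arbitrary; each
  loading column is flipped so its largest-magnitude element is positive,
  making scores reproducible across linear-algebra backends.
* **Projection.** Occurrences are projected with the *background* centring,
  scaling and loadings. New points never refit the PCA, so species scores
  live in the same space as the availability background.

Occurrence filtering mirrors standard herbarium-data practice: records with
coordinate precision strictly worse than 10 km are discarded (exactly 10 km
is kept), records outside the raster are dropped (nearest-pixel assignment,
with "outside" meaning farther than half a pixel diagonal from any centre),
and species with fewer than 5 records or fewer than 5 distinct pixels are
removed. One record per species per pixel is kept
(`dedupe_per_pixel()`) so collector revisits do not inflate density.

**Niche identity** is the per-axis mean of a species' deduplicated scores;
**niche breadth** is their per-axis standard deviation. The sample
(n − 1) standard deviation is used: the convention is the unbiased default
and the choice only rescales breadth by a factor common to all species.

# Niche overlap

`occupancy_grid()` follows the kernel occupancy construction for
environmental spaces: a product-Gaussian kernel density of the species'
scores evaluated at the cell centres of an R × R grid spanning the
background scores (R = 100 by default), optionally divided by the
background availability density so the result reflects preference rather
than availability, then renormalized to sum to one. Defaults that the
method's description leaves open, all configurable:

* bandwidth: Silverman's rule per axis on the species' own points, floored
  at 1/1000 of the axis extent so degenerate clouds stay usable;
* availability correction on by default, with the background density
  floored at its 1st positive percentile before division to avoid blow-ups
  at the fringe of the climate envelope;
* grid resolution R = 100.

Schoener's D between two grids is `1 − 0.5 Σ|z1 − z2|`: 0 for disjoint
occupancies, 1 for identical ones. `fit_overlap_models()` regresses D for
all species pairs on *same pollination mode* and *same island*:
intercept-only, each predictor alone, both, and their interaction, compared
by the standard Gaussian-likelihood AIC of ordinary least squares (ML
variance; k counts coefficients plus the variance). Two conventions
deliberately follow the source analysis: pairs are treated as independent
(no phylogenetic correction of the D regression — D is a distance between
a *pair*, so standard phylogenetic corrections do not apply), and a pair
"shares an island" when the two species' island sets intersect, the natural
reading for species spanning two islands. Pairs involving an
unknown-pollination species are excluded from models that use the
pollination predictor and retained in island-only models; the per-model `n`
column makes the resulting sample-size differences explicit, and AIC values
should only be ranked across models fitted to the same pairs.

# Regime histories: Mk models and stochastic mapping

Fitting a regime-dependent evolution model requires every branch to carry a
regime. Regimes are reconstructed by stochastic character mapping under
continuous-time Markov (Mk) models:

* **Pollination mode** (hummingbird / bat / mixed): all-rates-different
  (ARD) transition matrix, with *soft tip priors* encoding how each mode
  was determined — probability 1 for field-observed modes; 2/3 on the
  inferred state and 1/6 elsewhere for syndromes inferred from floral
  shape when the inferred mode is a specialist; 1/2 on mixed and 1/4 on
  each specialist when the inferred mode is the generalist; 1/3 each when
  unknown (`build_tip_priors()`).
* **Island** (Cuba, Hispaniola, Jamaica, Puerto Rico): symmetric (SYM)
  rates. Regimes must be exclusive, so each multi-island species is
  assigned one of its islands uniformly at random, re-drawn in every
  replicate iteration (`assign_single_island()`). The Lesser Antilles are
  not a state: the system's only Lesser-Antillean species also occurs on
  Jamaica, so the four-island state space covers all species.

`mk_loglik()` is the pruning algorithm with per-branch `exp(Qt)` (one eigen
factorization reused across branches, with a scaling-and-squaring fallback
for ill-conditioned eigenvector bases) and per-edge rescaling in log space,
so underflow cannot occur. Tip priors enter as tip partial likelihoods.
Three root treatments are available — uniform, stationary, and the
conditional-likelihood weighting of FitzJohn — with the FitzJohn weighting
as default; the original analysis does not state its root prior, and this
is the common default in the mapping literature. The choice is recorded in
the fitted object.

`sample_stochastic_map()` draws exact histories: root state from its
posterior, node states conditional on parents (downpass partials times
transition rows), then each branch's internal path conditional on its
endpoints by rejection-sampling forward CTMC paths. After 1000 rejected
attempts on a branch the sampler switches to uniformization, which is exact
and always terminates even for improbable endpoint pairs; virtual jumps are
collapsed so adjacent segments always differ in regime. Exactness is tested
by comparing node-state frequencies over 10^4 maps with marginal posteriors
computed independently (and those, in turn, against brute-force enumeration
on small trees).

# The six evolution models

Trait values (identity and breadth on each axis) evolve on the painted tree
under BM or OU. The parameter sharing follows the models' verbal
definitions: multi-regime BM gives each regime **its own diffusion rate**
σ²_r with a shared root state; multi-regime OU gives each regime **its own
optimum** θ_r with shared attraction α and rate σ².

`model_moments()` builds the exact Gaussian moments implied by a painting:

* BM: `C_ij = Σ_segments σ²(regime) · duration` over the shared root-to-tip
  path; mean = root state.
* OU (Hansen construction): the expected tip value is the exponentially
  weighted average of the optima along the tip's root path,
  `E[y_i] = e^{−αT_i} θ_root + Σ_seg (e^{−α(T_i − t_end)} −
  e^{−α(T_i − t_start)}) θ_seg`, and
  `V_ij = σ²/(2α) · e^{−α d_ij} (1 − e^{−2α s_ij})` with `s_ij` shared time
  and `d_ij` phylogenetic distance.

Two OU root conventions exist in the literature. The default here is the
**non-stationary root fixed at the optimum of the root regime** (the second
factor above); a stationary-root variant (`stationary_root = TRUE`) drops
that factor. The default keeps OU1 continuously connected to BM1 as α → 0,
which the tests exploit (`1 − e^{−2αs}` is evaluated with `expm1`, so the
α = 10⁻⁸ limit matches BM to 10⁻⁴ without cancellation).

Bivariate trait sets use the Kronecker-structured generalization with the
same regime layout: a full symmetric 2 × 2 rate matrix (per regime for BM)
and a **diagonal** α for OU. Diagonal α keeps the free-parameter count k
small relative to n = species × traits = 70 and makes the bivariate moments
collapse exactly onto the univariate ones when the off-diagonal rate is
zero (a property the tests assert); a full α matrix adds little at this
sample size.

**Fitting.** Optima/root states enter the mean linearly and the overall
rate scale multiplies the covariance, so both are profiled out by
generalized least squares; only low-dimensional "shape" parameters remain:
none for BM1 (closed form), the rate ratios for BM3/BM4, log α for
univariate OU (a deterministic 15-point grid on
`[10⁻⁴, 50]/tree-height` bracketing a golden-section refinement — this
covers phylogenetic half-lives from effectively-Brownian to
effectively-white-noise), and (α₁, α₂, rate-matrix shape) for bivariate OU.
Multivariate shapes start from the corresponding univariate solutions (a
warm start that in practice lands on the same optimum as multi-start
searches) plus optional random restarts; `fit_evomodel()` defaults to 5
restarts, while the replicate engine uses the deterministic warm starts
alone, which keeps the 1000-iteration design reproducible. Rank-deficient
regime designs (a regime that a particular map barely visits) are handled
by the QR fit: the unidentifiable optimum is reported `NA` rather than
destabilizing the likelihood.

**Model comparison.** `aicc()` applies
`AICc = AIC + 2k(k+1)/(n − k − 1)` with `n` = species × number of traits
(35 or 70 here) and k counting every free parameter including the profiled
ones: BM univariate k = R + 1, OU univariate k = R + 2, BM bivariate
k = 3R + 2, OU bivariate k = 2R + 5 for R regimes. Akaike weights are
`w_i ∝ e^{−Δ_i/2}`. AICc ≥ AIC holds whenever n > k + 1, which the code
enforces.

# Uncertainty propagation

`run_replicates()` pairs iteration *i* with tree *i* (cycling through the
tree sample) and with jackknife draw *i*: half of each species'
deduplicated records (at least 2) are kept, niches recomputed, the island
assignment re-drawn, both Mk models refit, one stochastic map drawn per
regime source, and all six models fitted on each of the eight trait sets
(identity and breadth on PC1, PC2, PC1+PC2, and identity+breadth per axis).
Pairing tree *i* with jackknife *i* — 1000 iterations in the reference
design rather than a 10⁶ cross product — matches how the uncertainty
sources are usually combined; crossing them changes the budget, not the
estimand. One map is drawn per iteration per regime source: averaging many
maps within an iteration would shrink the mapping uncertainty that the
design intends to propagate. The summary reports the mean weight per model
and trait set with an empirical 2.5–97.5 percentile interval, which is the
natural Monte-Carlo reading of a 95% CI. Iterations that fail (a degenerate
jackknife, say) are logged and skipped; more than 10% failures aborts the
run with the log.

# The synthetic study system

Because the original inputs (climate rasters, herbarium and aggregator
records, posterior tree samples) are not redistributable as flat files,
`simulate_dataset("paper-shape")` generates a study system with the same
statistical structure, and every stage is tested against it:

* **Raster**: 3458 pixels × 20 variables built as linear mixtures of 2
  latent factors plus independent noise, so correlation-PCA concentrates
  variance on two axes. The noise level (sd 0.9 against unit-variance
  factors) puts the first two axes near 70% of total variance, the regime
  observed for real Antillean bioclim layers. Four contiguous island blocks
  with unequal sizes (45/32/13/10%) carry distinct latent offsets, making
  "same island → more similar available environment" an injectable, known
  effect.
* **Trees**: a birth–death tree (35 tips, depth 1, birth 1, death 0.5)
  rescaled to unit depth; the pseudo-posterior is generated by jittering
  internal node ages with lognormal noise (sd 0.1) under their parents,
  which keeps every tree ultrametric with the same topology — the analysis
  only needs a set of plausible trees, not a real MCMC sample.
* **Regime histories**: pollination mode evolves under an ARD matrix from
  a hummingbird-specialist root (transitions toward bat and mixed more
  frequent than reversals); islands under a symmetric matrix. About 4/35
  species get a second island, 15/35 modes are downgraded to "inferred"
  and one to "unknown", mirroring the metadata composition.
* **Traits**: niche centres evolve under OU1 in PC space (half-life a
  quarter of tree depth, stationary sd 0.8), so the pipeline's model
  selection has a known answer — OU1 — and the acceptance run reproduces
  the qualitative headline result. Log niche widths evolve under a mild
  OU1 around log 0.45. Centres are clamped to the central 96% box of the
  background scores so every Gaussian niche lies in the attainable space.
* **Pollinators**: 14 hummingbird and 8 nectarivorous bat species with
  wide niches (isotropic sd 1.0–1.8 in score units, centres near the
  middle of the climate envelope) and 8–1219 records each; about half span
  all four islands and the rest are restricted to subsets, so the
  pollinator overlap regression has a non-degenerate island predictor.
  Pollinator records pass the same filters as plants except the
  5-record/5-pixel species minimum, which is not imposed on pollinator
  data. Wide pollinator niches make the empirical range-inclusion finding
  (plant niches nested inside their functional groups' envelopes)
  reproducible in the synthetic system.
* **Occurrences**: per species, 6–116 records (lognormal around 24),
  sampled with replacement from the species' islands' pixels with
  probability proportional to an isotropic Gaussian at the pixel's
  (PC1, PC2). Sampling within islands is what injects the same-island
  overlap effect without touching the trait model.

What the generator does **not** emulate: spatial autocorrelation of
collection effort within pixels (pixels are exchangeable within the niche
density), distinct pollinator occurrence processes (pollinator tables pass
through the same machinery with the species-level minima disabled), niche
truncation at hard range edges, and real posterior topological uncertainty
(topology is fixed; only node ages vary). Tests passing on this system
therefore certify the *machinery* — likelihoods, samplers, estimators,
selection logic — not the field realism of any particular dataset.

# Problem sizes and tolerances in the test-suite

The suite runs the generating-model recovery experiments at 100 datasets
per generating model on 35-tip trees and parameter recovery at 100 tips ×
100 replicates — sizes at which the expected success rates (≥ 80% family
recovery, < 15% median rate error, ≥ 90% optima ordering) are stable.
The pipeline determinism check runs the paper-shape preset at 50
iterations, which exercises every stage including all eight trait sets.
Exact oracles (path enumeration, state enumeration, closed forms) are
asserted at 10⁻⁸–10⁻¹⁰; Monte-Carlo checks use three-standard-error bands.

# Known limitations

* The overlap regressions treat species pairs as independent; pairs
  sharing a species are correlated, so the reported p-values are
  anticonservative. The AIC comparison is unaffected in ranking but
  inherits the same non-independence.
* Multi-regime OU shares α and σ² across regimes; a regime-specific α or
  rate (or simultaneous multi-regime evolution for two-island species) is
  outside the model family compared here.
* The bivariate OU uses a diagonal α; correlated selection toward the
  optimum is not modelled.
* Breadth is analysed on its raw (sd) scale by default, the literal
  reading of "niche breadth"; a log-scale option exists on the generator
  side and positive-valued traits may warrant it.
* The Mk machinery assumes rate homogeneity through time within a regime
  class; no hidden-rate or correlated-character extensions.
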