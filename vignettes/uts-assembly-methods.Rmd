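---
title: "Methods: assembly processes and city specificity of transit-surface microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly processes and city specificity of transit-surface microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `utsassembly`, the assumptions
they make, the tunable parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

# The scientific setting

Transit-surface microbiomes are open, high-turnover communities fed by
travellers and by other surfaces. Two forces compete in their assembly:
*stochastic* processes (dispersal, drift, random colonization from a shared
metacommunity) and *deterministic* niche processes (selection by the local
environment — here summarized by characteristics of the host city such as
climate, latitude, or population). The package quantifies the balance of
these forces and then asks the complementary question: which genera are
city-specific enough that city characteristics can be read back off the
community?

# Neutral community model

## Model and assumptions

Under neutral assembly, a local community of effective size `N_L` coupled
to a metacommunity by immigration rate `m` has, at stationarity, taxon
relative abundances distributed `Beta(Nm·p_i, Nm·(1−p_i))`, where
`Nm = N_L·m` and `p_i` is the taxon's metacommunity relative abundance.
A taxon is *detected* in a sample when its abundance exceeds the detection
limit `d`; its predicted occurrence frequency across samples is the upper
beta tail `F̂_i = 1 − I_d(Nm·p_i, Nm·(1−p_i))`.

Assumptions worth keeping in mind: all taxa are demographically equivalent;
`p_i` is estimated by the mean observed relative abundance; detection is
approximated by a hard threshold at `d` rather than by the exact
probability of a positive count.

## Numerical choices

* **Detection limit** `d = 1/N` with `N` the mean sequencing depth. This is
  the convention of the widely used R implementations of the model and is
  stable under uneven depth; the per-sample minimum relative abundance is a
  noisier alternative.
* **Estimator**: `Nm` minimizes the sum of squared residuals between
  observed frequencies and `F̂` on a deterministic coarse-to-fine search —
  120-point log-grid over `[1e-2, 1e7]` followed by golden-section
  refinement in the bracketing interval. No stochastic restarts, so fits
  are exactly reproducible. The objective is unimodal in `log(Nm)` in all
  regimes we examined.
* **Envelope**: the 95% interval around `F̂` is the Wilson score interval
  with `n` = number of samples, computed on the predicted frequency. Genera
  above the envelope occur more often than neutral prediction (candidate
  dispersal specialists), genera below occur less often (candidate niche
  restriction).
* Taxa never observed are excluded (they carry no frequency information);
  taxa observed in every sample at `p ≥ 1` (degenerate single-taxon tables)
  cannot enter the beta CDF and are excluded with a warning path.

## Known bias

The threshold-detection approximation is not exact: the true detection
probability at depth `N` is `1 − E[(1−w)^N]`, which is smoother than the
indicator `w > 1/N`. On simulated neutral panels (150-genus lognormal
metacommunity, 200 samples, depth 5×10⁴, `Nm = 500`) this biases the
fitted `Nm` upward by roughly 10%, occasionally approaching the 15%
relative-error mark across seeds. The bias is a property of the model
family, not of the optimizer; we keep the standard formulation because it
is what the field fits and interprets.

# Stochasticity: MST and β_RC

## Null model

Each null replicate reassembles every sample independently under a
random-zero expectation: the sample's observed richness of taxa is drawn
without replacement with probability proportional to taxon occupancy; one
individual is placed on each drawn taxon; the remaining observed total
abundance is distributed multinomially in proportion to regional (summed)
relative abundance. Richness and total abundance are conserved exactly in
every replicate — asserted in the tests. Bray-Curtis dissimilarity is the
community metric throughout (the abundance-based metric used by the rest
of the analysis); the null algorithm and the metric are both configurable
because the field's null-model packages offer several variants and no
single combination is canonical.

## Statistics

With observed dissimilarity `D`, null mean `E`, and maximum `d_max = 1`:

* `MST = D/E` when `D ≤ E`, `(d_max−D)/(d_max−E)` otherwise; both branches
  equal 1 at `D = E` and decrease toward 0 as the observation departs from
  the null in either direction. Values above 0.5 are read as
  stochasticity-dominated. Degenerate null expectations (`E = 0` with
  `D > 0`, or `E = d_max` with `D < d_max`) are mapped to 0 with a warning.
* `β_RC` is the rank of `D` within the null ensemble rescaled to [−1, 1],
  ties counted as half. ±1 means the observation lies outside the whole
  ensemble.

Group summaries report within-group mean MST and a β_RC grade histogram
(±0.95 cut-offs), the usual way the bimodality of deterministic pair
structure is displayed.

`n_null` defaults to 1000; the test-suite runs use 100 replicates, which
changes per-pair `E` by < 0.02 on the panels used (verified by a
Monte-Carlo stability test). β_RC resolution is `2/n_null`.

## Interpretation caveat

The β_RC of a *neutral* community is close to 0 only when the generator's
between-sample variance matches the null's sampling variance. Our neutral
acceptance panels therefore use strong dispersal coupling (`Nm = 5000` at
depth 2000), the regime in which drift variance is small against sampling
noise; weaker coupling inflates |β_RC| even under neutrality while MST
remains the robust discriminator.

# Source tracking

`em_fit()` maximizes the joint likelihood of source counts
(`y_k ~ Multinomial(γ_k)`) and the sink (`x ~ Multinomial(Σ_k α_k γ_k)`)
by EM; the unknown source's profile is estimated from attributed sink
counts alone. The log-likelihood is non-decreasing by construction and is
asserted at every iteration.

The mixture has a known identifiability ridge: the unknown component can
absorb part of any known source's contribution without changing the sink
likelihood. The fixed point the EM reaches therefore depends on where the
unknown starts. We initialize the unknown profile from the sink mass a
preliminary known-sources-only fit cannot explain (clipped residual,
renormalized), with mixing proportions uniform over K+1. On planted
mixtures (α = 0.6/0.3/0.1-unknown, 120 taxa, depth 10⁵) this recovers each
proportion within ±0.02; a flat unknown start instead inflates the unknown
by ~0.15. Tolerances: `tol = 1e-6` on the log-likelihood, `max_iter = 1000`,
pseudocount `1e-10` on profiles.

This is a deliberately simplified fixed-point EM, not the full variational
scheme of the published fast source-tracking tool; multi-sample sources are
pooled into one count vector per source surface.

# Transfer random forests

## Forest

Trees are CART classification trees: gini impurity, `mtry = ⌈√F⌉` features
per split, bootstrap per tree, default 100 trees, depth cap 30. They are
implemented natively (C++ via Rcpp) because the transfer step needs
operations wrapped forests do not expose: routing new samples to leaves,
growing subtrees at leaves, and bottom-up pruning. Determinism contract:
`(data, config, seed)` → identical trees; split ties break toward the
lowest feature index, then the lowest threshold. Feature lists are sorted
internally, so the caller's feature order never changes a result.

## SER transfer

Structure expansion/reduction adapts a base forest to a target domain:

1. **Expansion** — target samples are routed down each tree; any leaf
   reached by ≥ `min_leaf` (default 5) target samples grows a CART subtree
   on those samples.
2. **Re-estimation** — leaf class distributions are re-estimated from
   target counts with Laplace (+1) smoothing wherever at least one target
   sample reaches; leaves the target never visits keep their source
   distribution (a uniform Laplace re-estimate there would erase the source
   knowledge the transfer is meant to retain).
3. **Reduction** — bottom-up, a subtree collapses to a leaf labelled by the
   target majority whenever the collapsed leaf's target misclassification
   is no worse than the subtree's.

Only SER is implemented; threshold re-tuning (the STRUT variant) is out of
scope.

## Evaluation design

For a target surface: BM trains on all samples of the other surfaces
(across cities — the reading that matches "heterogeneity from different
surface types"); IM trains on the target training portion; TM adapts BM to
the same portion. All three are scored by macro-averaged one-vs-rest AUROC
(rank statistic, ties credited ½) on the same validation samples. The
multiclass averaging scheme is our choice; single-number AUROCs for
many-class problems are reported without a scheme in much of the applied
literature. Protocols: city-stratified 10-fold cross-validation, or a
stratified 20%-train/80%-test split; both repeated, with repeat `r` using
seed `base + r` shared across BM/IM/TM so comparisons are paired. The
20%-train reading of the ambiguous "20%/80%" split is adopted because the
small-training regime is what motivates transfer in the first place.

ΔAUROC city specificity of genus `g` is the mean over repeats of
`AUROC(TM, all features) − AUROC(TM, features∖{g})`, with the base model
refit per feature subset so the comparison is between complete pipelines.
Candidate features are preselected as the `k = 100` genera with the
highest relative-abundance variance (ties lexicographic).

# City-characteristic models

Characteristics are sample-level labels inherited from the sample's city.
Continuous characteristics are discretized to three equal-width bins over
`[min, max]` at the *city* level (low/medium/high; lowest edge nudged down
by 0.1% of the range; right-inclusive intervals). IM and TM classifiers
use the same forest machinery; accuracy is the per-sample fraction correct,
reported per city, with cities under 20 target-surface samples flagged.
The control analysis draws random feature sets of equal size from the
non-selected genera and compares accuracies with a one-sided paired
Wilcoxon signed-rank test, paired by repeat.

# Association statistics

Shannon diversity (natural log), PCoA (Gower double-centering; negative
eigenvalues reported, not corrected), PERMANOVA (pseudo-F, permutation
p-values of the form `(b+1)/(m+1)`) and Mantel tests (Spearman, 999
permutations) are computed through the standard community-ecology packages
(`vegan`, `ape`) behind this package's interfaces; the test-suite
cross-checks the PERMANOVA R² against a direct sum-of-squares
decomposition of the dissimilarity matrix.

Two choices the literature leaves open:

* **MST vs characteristics.** A pairwise stochasticity quantity has no
  canonical PERMANOVA formulation; we feed `1 − MST` as the dissimilarity
  with sample-level factors. Sequential (terms-wise) partitioning is the
  default for multi-factor summaries — the per-factor R² then sum within
  the total, matching the convention of reporting a combined explained
  fraction — with marginal single-factor tests available.
* **Characteristic distances** for the Mantel panel: standardized Euclidean
  for continuous characteristics, 0/1 mismatch for categorical ones.

# The synthetic generator

## What it emulates

* **Neutral assembly**: samples drawn from the stationary Sloan marginal —
  `Dirichlet(Nm·p)` composition, multinomial counts at the configured
  depth. This replaces explicit birth-death simulation for speed; an
  individual-based Moran simulator (`simulate_neutral_moran()`) is provided
  as a slow cross-check and agrees with the stationary sampler at small
  scale.
* **Niche filtering**: Gaussian kernels `exp(−(e−o_i)²/2σ²)` on a per-city
  environment value derived from the climate category; `σ → ∞` recovers
  the neutral generator (tested distributionally over 100 seeds).
* **Surface domain shift**: per-surface lognormal multiplicative taxon
  biases (`surface_shift_sd`, default 0.4 on the log scale; 0 makes
  surfaces exchangeable).
* **Planted signatures**: named taxa multiplied by an effect size in
  samples whose metadata matches a characteristic level — the ground truth
  for specificity mining and characteristic prediction.
* **City characteristics**: climate categories assigned round-robin over a
  shuffled level order (so every level is represented once a panel has ≥ 5
  cities); continuous characteristics drawn correlated with the climate
  index (default correlation 0.5), giving the association stages realistic
  collinearity.
* **Source/sink mixtures**: multinomial draws from convex combinations of
  source profiles plus a freshly drawn unknown component.

Default panel: 8 cities × 4 surfaces × 25 samples, 150 genera, depth
2×10⁴, `Nm = 500` — sized so a complete demonstration run stays
interactive on one CPU.

## What it does not emulate

Sequence-level error and taxonomic misassignment; phylogenetic structure;
temporal autocorrelation between sampling campaigns; compositional
artefacts of bioinformatic pipelines; uneven sampling depth. Passing tests
on these panels therefore validate the statistical machinery and its
discriminating power under known truth — they do not certify performance
on any particular real data set.

## Study conditions used by the automated checks

Parameter-recovery: `Nm = 500`, 200 samples, depth 5×10⁴, 150 genera.
Stochasticity discrimination: 30-sample panels, 80 genera, depth 2000,
100 nulls; neutral at `Nm = 5000`, niche at `σ = 0.3`. Domain shift:
5 cities × 4 surfaces × 12 samples, 60 genera, shift sd 1.5 — a strong
between-surface heterogeneity regime in which the base model is visibly
degraded. Specificity mining: one genus planted at effect 8 among 15
candidates. Characteristic prediction: one 2-genus signature block per
climate level at effect 8. These sizes keep the full suite to a few
minutes; enlarging the panels tightens every margin.

# Limitations

* The NCM fit inherits the threshold-detection bias described above and
  provides no confidence interval on `Nm` itself.
* MST/β_RC conclusions depend on the chosen null algorithm and metric;
  alternatives (e.g. phylogenetic nulls) are out of scope.
* The source-tracking EM is a point estimator on a partially unidentifiable
  model; its unknown-source estimate should be read as a lower-bound-style
  attribution, not a posterior.
* Forests are trained on relative abundances without further normalization
  (trees are monotone-invariant); compositional effects between very
  different sequencing depths are not modelled.
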