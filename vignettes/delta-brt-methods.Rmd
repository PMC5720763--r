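---
title: "Delta log-normal boosted regression trees: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta log-normal boosted regression trees: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(deltaboost)
```

## The problem

Trawl-survey catch rates (CPUE) of marine species are zero at most stations
and long-tailed where positive. Neither a Gaussian nor a single count model
describes such data well; fisheries science routinely splits the problem in
two. deltaboost fits that two-part — *delta*, or hurdle — model with boosted
regression trees (BRTs):

* an **occurrence** component: a bernoulli ensemble fitted to
  presence/absence over all stations, predicting `p(occurrence)`;
* a **positive-abundance** component: a Gaussian ensemble fitted to
  `log(CPUE)` over the positive stations only.

A grid cell's abundance index is the product

```
combined_index = p_occurrence × s · exp(f_gaussian)
```

where `f_gaussian` is the log-scale prediction and `s` is **Duan's smearing
estimator**, the mean of the exponentiated log-scale training residuals.
Naively exponentiating a log-scale prediction estimates the conditional
*median* and is biased low for the mean; smearing corrects this without
assuming normal residuals (for exactly normal residuals it converges to
`exp(σ²/2)`). The natural log is used throughout; the reverse transform is
never `exp` alone.

When the response is *not* zero inflated the hurdle is skipped and a single
ensemble (Gaussian or Poisson, `family_single`) is fitted; its
response-scale prediction is the combined index and `p_occurrence` is
reported as 1.

## Zero inflation rule

The delta pathway is chosen automatically when the proportion of exact zeros
is at least `zi_threshold` (default 0.5). A proportion-of-zeros rule was
chosen over alternatives (e.g. a zero median, or a dispersion test) because
it is transparent, monotone in its threshold, and directly reflects the
quantity the hurdle models — the threshold is exposed in `brt_config()` for
users whose data sit near the boundary.

## Fitting and hyperparameter search

Each component is a standard stagewise gradient-boosted tree ensemble (the
xgboost engine, single-threaded for reproducibility) with three
hyperparameters in the field's usual vocabulary: tree complexity `tc`
(interaction depth), learning rate `lr` (shrinkage) and bag fraction `bf`
(row subsample per tree). The search loops bag fraction nested within
learning rate nested within tree complexity and fits every combination for
both components.

**Stopping rule.** Tree count is chosen by cross-validation with an explicit
deterministic rule: trees are grown in blocks of 50; after each block the
mean k-fold held-out deviance is computed; growth stops when the curve has
not improved for 2 consecutive blocks or at 10,000 trees; the selected size
is the argmin of the block-level curve, and the final ensemble is refitted
on all rows at that size. Deviance is defined per family so comparisons are
well posed: `-2 ×` mean Bernoulli log-likelihood (bernoulli), mean squared
error (gaussian), mean unit deviance (poisson). Reaching the minimum in the
very first block triggers a "lr may be too high" warning rather than an
error.

**Selection.** The winning combination minimises the CV deviance; ties break
by fewer trees, then lower `tc`, then lower `lr`, then lower `bf` — a total
order, so the selection cannot depend on how the candidate lists were
written. CV deviance was preferred over CV correlation or training AUC as
the criterion because it is the quantity the stopping rule already
estimates, is defined identically for every family, and penalises
miscalibration, not just misranking; the alternatives are recorded in the
model report so a user can audit the choice.

**Folds** (default 10, stratified on the response for the occurrence
component) are derived from the run seed, so a single integer reproduces the
entire fit → predict pipeline bit-for-bit.

**Simplification.** Backward elimination with the 1-SE rule: repeatedly
refit without each remaining variable, drop the one whose absence least
increases CV deviance, and stop when even the best removal worsens CV
deviance by more than one fold standard error of the current model. The
1-SE rule errs towards smaller models only when the data cannot
distinguish them — a conservative reading of "performs better with
variables omitted".

**Feasibility.** Boosting subsamples `floor(bf × n)` rows per iteration;
`bfcheck()` reports the smallest bag fraction on a 0.01 grid whose
subsample still holds `min_train_rows` rows (default 21, the smallest
per-iteration training set the fitter is required to accept; the constant
is configurable and deliberately conservative). The computation is integer
arithmetic (`(k·n) %/% 100`), so no floating-point rounding can shift the
boundary.

**Missing values.** Stations with missing predictors are retained — the
tree learner routes them through default directions learned per split.
Prediction cells with a missing predictor yield missing outputs, never
silent zeros.

## Diagnostics

All diagnostics are computed on the link scale; response-scale rendering is
a plotting option (the exponentiated, smeared Gaussian curve is
rank-equivalent to its link-scale version, which the tests assert).

* **Relative influence**: reduction-in-loss attribution summed over every
  split using a variable, normalised to percentages summing to 100.
* **Partial dependence**: the mean prediction over training rows with one
  variable clamped to each of 100 evenly spaced values spanning its sampled
  range.
* **Dot plots**: each training row's full prediction centred on the mean
  prediction, against the row's value of one variable — the spread shows how
  much the other variables modulate the effect.
* **Interaction strength**: the mean squared residual of the two-way
  partial-dependence surface on a 20 × 20 lattice after removing additive
  row/column structure; exactly 0 for an additive pair. Grid sizes (100 and
  20 × 20) trade resolution against prediction cost and are configurable.
* **Model report**: one long-format CSV holding every combination's CV
  metrics, the selected combinations, the simplification trail, influence,
  top interactions, training metrics, the smearing factor, the
  zero-inflation decision and the seed.

## Representativeness (RSB)

For each explanatory variable, sample and grid values are binned into 10
equal-width bins spanning the **grid's** range — the grid is the prediction
universe, so sample values outside it clamp into the end bins. A cell's
score for a variable is `|sample_freq − grid_freq|` of the cell's own bin;
the total is the sum over variables. A survey that is an exact stratified
replica of the grid scores 0 everywhere; high totals flag cells whose
conditions the survey under- or over-represents. The bin count is the main
tuning knob: fewer bins are more forgiving, more bins demand finer coverage.
A signed variant (positive = under-sampled) is available for map reading but
is not the default, which follows the absolute-difference definition.

## Conservation surfaces and the decision-support tool

`combine_subsets()` rescales each species/subset surface to unit maximum
before the weighted sum, so an abundant subset cannot swamp a rare one; the
amalgamation formula (weighted sum of unit-max-scaled surfaces, weights
defaulting to 1) is this package's choice, with unit-sum scaling behind a
flag.

The closed-area tool ranks cells under one of four schemes — combination
(mean of unit-scaled abundance and reversed unit-scaled stressor), biomass,
effort (ascending stressor, ties broken towards high abundance so free
cells are taken first), conservation — and accumulates ranked cells until
each species' **Bpa** escapement target is met. The target defaults to
`(1 − HRMSY) × total predicted biomass`: escapement biomass is the share of
the stock that must remain unharvested and `HRMSY` the harvestable
fraction. The formula is injectable (`bpa_fn`) because management bodies
may prescribe an absolute tonnage instead. The combination aggregator is
the arithmetic mean of the two unit-scaled terms (endpoints 0 = max
stressor, no abundance; 1 = no stressor, max abundance); a geometric-mean
variant is available behind a flag. Multi-species plans cascade in at-risk
order: each later species is first credited with its biomass inside earlier
closures, then adds its own cells. Closures are cell sets, not polygons —
contiguity is not enforced.

**A property that does not hold.** One might expect the effort sort to
always yield the lowest effort overlap. It does not: greedy per-cell effort
minimisation is not total-effort minimisation. With escapement targets at
realistic harvest rates (`HRMSY` ≈ 0.1, so targets are ~90% of total
biomass) the effort sort — blind to abundance — needs many more cells to
reach the target and usually ends up overlapping *more* effort than the
abundance-aware combination sort (in roughly 90 of 100 random toy
instances). The package therefore reports overlap per scheme and makes no
ordering promise between schemes.

## Uncertainty loops

`run_loops()` repeats the identical run with seeds `base_seed + k` and
collates per-cell mean, standard deviation (n−1 denominator) and coefficient
of variation of the combined surface, min/mean/max/variance of influence,
and pointwise partial-dependence envelopes. Simplification defaults to off
inside loops so the variable set stays constant and envelopes are
comparable; with it on, a variable absent from a run counts as influence 0.
A forced-identical-seed mode exists purely as a self-test: its CV surface
must be exactly zero.

## The synthetic study system

The generator builds what the method assumes: each environmental field is a
gentle random linear trend (`trend_sd = 0.3`) plus Gaussian-smoothed white
noise (`σ = 2` cells), standardized. The trend is kept weak deliberately —
all fields draw their trends from the same two spatial directions, so a
dominant trend makes nominally independent fields strongly collinear and
the "pure noise" controls stop being controls; with these weights the four
fields are effectively independent (typical max |r| ≈ 0.4). The default
truth has two active covariates in both components and two pure-noise
controls; the occurrence intercept (−0.5) yields ~50–60% zero catches and
the log-scale noise (sd 0.7) a long right tail — the stated hallmarks of
trawl-survey CPUE. The closed-form expected abundance,
`plogis(η_occ) × exp(η_abn + σ²/2)`, is exported per cell so recovery is
measurable exactly. Effort surfaces mix the abundance field's normal scores
with independent noise to hit a requested Spearman correlation.

What the generator does **not** emulate: spatial autocorrelation of catches
beyond what the smooth covariates induce, preferential sampling feedback,
observation-effort differences between stations, vessel/gear effects, and
temporal structure. Passing tests on this system show the machinery
recovers a known hurdle signal under clean conditions; they do not show the
model handles survey artefacts real data may carry.

## Problem sizes used in the tests

The shipped tests exercise a 20 × 20 cell landscape with 300 stations for
unit-level checks and the full 40 × 40 / 1,000-station system for the
recovery checks (10 seeded repeats); decision-support properties run on 100
random instances of ≤ 200 cells and 2–4 species, with brute-force oracle
comparisons on 6–12-cell instances. These sizes make the whole suite run in
a few minutes while leaving the recovery problem genuinely nontrivial
(effective sample ~170 independent patches per field).

## Numerical and degenerate-input choices

* Bernoulli deviance clamps probabilities to `[1e-12, 1 − 1e-12]`.
* Closure accumulation uses a relative tolerance of `1e-9` at the target
  boundary; all ordering ties break by cell index, so plans are
  deterministic.
* A constant (degenerate) response is fitted but flagged: influence is
  reported as all-zero with a warning rather than invented.
* Constant grid variables cannot be binned and are skipped with a warning
  in RSB scores.
* All-zero surfaces scale to all-zero (with a warning), and a zero-total
  stressor makes effort overlap `NA` with a "no effort data" legend.
* Raster cell sizes are inferred as the modal centroid gap (ties to the
  smallest), tolerating missing cells; centroids must sit on the lattice
  within 1e-6°.

## Known limitations

* The engine's CV curve is evaluated at block (50-tree) resolution; tree
  counts are multiples of 50.
* Coastline input is GeoJSON and raster export is the plain-text ESRI
  ASCII grid (square cells); projected coordinate systems are out of scope
  and coordinates are taken as given in WGS84 degrees.
* Greedy closures are not optimal reserve designs; no
  contiguity/compactness constraints.
* The loop varies only the stochastic elements of identical runs; it is not
  a bootstrap of the input data.
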