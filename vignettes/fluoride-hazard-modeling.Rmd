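---
title: "Modeling groundwater fluoride hazard and population exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling groundwater fluoride hazard and population exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorisk)
```

## The problem

Naturally occurring (geogenic) fluoride above the WHO drinking-water
guideline of 1.5 mg/L causes dental and skeletal fluorosis, and groundwater
is rarely tested in many of the affected regions. Given a compilation of
point measurements of fluoride in wells and springs, gridded environmental
covariates (climate, soil, topography, lithology), gridded population, and
country-level rates of domestic use of untreated groundwater, `fluorisk`
estimates

1. a **hazard map**: the probability, per grid cell, that groundwater
   fluoride exceeds 1.5 mg/L, and
2. the **population at risk**: how many people consume untreated groundwater
   in hazardous areas, by three estimators that bracket the truth.

Because such measurement compilations are typically protected, the package
also ships a synthetic-data generator with a *known* ground truth. Every
stage of the pipeline is exercised and tested against that truth; nothing in
the package depends on access to real data.

## Data preparation

Wells frequently carry replicate measurements. Replicates are collapsed to
their arithmetic mean **before** binarization (`dedupe_wells()` then
`binarize()`); the two operations do not commute, and labeling replicates
individually would leak duplicated information into training. Exceedance is
strict — a measurement exactly at 1.5 mg/L is labeled 0 — matching the
convention that prevalence is the share of measurements *above* the
guideline; the threshold is a parameter throughout.

Covariates are looked up at each well's containing grid cell
(`extract_covariates()`), with half-open `[x0, x1)` cell intervals and
points on the grid's maximum boundary assigned to the last cell. Points
outside the grid, or hitting a missing cell in any band, are dropped with a
logged count (how the original compilation handled these is not recorded;
dropping is this package's choice). Coordinates are assumed to be in the
grid's coordinate system — reprojection is a preprocessing responsibility.

Mixed-resolution covariate stacks (e.g. ~1 km climate and ~250 m terrain)
are harmonized by block replication of the coarse bands onto the finest
grid (`harmonize_stack()`); values are never interpolated, so every band's
value set is preserved exactly.

## The class-balanced random forest

Exceedance data are heavily imbalanced (≈10% positives). A forest bagged
from the raw rows would see ~90% negatives per tree and buy specificity at
the price of sensitivity. `train_balanced_forest()` instead grows each of
its trees (1001 by default; `floor(sqrt(p))` candidate features per split)
on an **equal-count stratified bootstrap**: the minority-class count drawn,
with replacement, from *both* classes. Sampling the minority class
preferentially at a rate of one minus the prevalence (0.898 at prevalence
0.102) is equivalent in expectation; the equal-count form is used because
it is exactly verifiable from the per-tree in-bag counts, which the test
suite audits.

Two probability readings are provided (`forest_config(tree_type = )`):

* `"probability"` (default): trees store terminal-leaf class fractions and
  the forest averages them — a probability machine. Leaves default to a
  minimum of 10 samples.
* `"classification"`: trees vote and the score is the fraction of trees
  voting exceedance; leaves default to 1 sample.

The two coincide as leaves shrink to a single sample. The probability
reading is the default because the product of this workflow is a
*probability* map, and downstream machinery (the sensitivity–specificity
crossover, the hybrid exposure cutoff at half the crossover) presupposes
approximately calibrated scores. At moderate sample sizes (thousands of
wells) hard-vote fractions of fully grown trees systematically under-score
the minority class — in our synthetic conditions the pooled crossover drops
to ≈0.43–0.45 under voting versus ≈0.45–0.49 under leaf-fraction averaging,
with the balanced-Bayes oracle at ≈0.53 — a finite-sample calibration bias
that disappears at the hundreds of thousands of wells where both readings
give a crossover of ≈0.5.

**Feature selection** (`rfe_select()`) is recursive feature elimination: fit
the balanced forest, record its out-of-bag balanced error (SD by the
binomial approximation `sqrt(e(1-e)/n)`), drop the 20% least-important
features (re-ranked every iteration — the conservative choice when the
original procedure's ranking schedule is unrecorded), and repeat down to
one feature. The chosen set is the *smallest* whose error is within one
standard deviation of the minimum across iterations. Importance defaults to
permutation importance (decrease in out-of-bag accuracy when a feature is
shuffled), with ranger's bias-corrected impurity score available as
`importance = "impurity_corrected"`; an impurity-based score corrected for
category-count bias is under-specified as an exact numerical target, so
only rankings are ever asserted. **Node size** (`tune_min_node_size()`) is
tuned over 1–5 by cross-validated balanced accuracy, ties to the smallest.

## Evaluation

`cross_validate()` implements repeated stratified Monte-Carlo
cross-validation: 100 (default) random 80/20 splits in which both
partitions hold the pooled exceedance prevalence *exactly* (class counts
are rounded, not sampled), a fresh forest per repetition, and per-repetition

* sensitivity, specificity, balanced accuracy at the 0.5 threshold,
* rank-based (Mann–Whitney, midrank tie-corrected) AUC,
* **balanced kappa**: the majority class of the test set is down-sampled to
  the minority size, accuracy on the balanced subset is converted by
  `kappa = (acc - NIR)/(1 - NIR)` with NIR = 0.5 (so `kappa = 2*acc - 1`
  identically), and the result is averaged over ten seeded draws.

The **crossover cutoff** — the probability threshold where sensitivity
equals specificity, the natural operating point of a balanced model — is
located on the pooled held-out predictions by minimizing
`|sensitivity - specificity|` over the unique score values (ties resolve to
the midpoint of the tied thresholds). Pooling rather than averaging
per-repetition crossovers is a design choice; the two agree closely in
practice. `stratified_metrics()` recomputes the confusion metrics within
depth bins or region labels to check that performance does not collapse in
strata the predictors do not encode.

## From hazard to exposure

`predict_map()` applies the fitted forest to every cell of the harmonized
stack (in memory-bounded chunks; missing data in any selected band
propagates to nodata, and the nodata count is reported).
`area_fraction_above()` summarizes the areal share of a region above a
probability cutoff, optionally weighted by a per-cell area raster (the
synthetic tests use planar equal-area cells; a latitude-dependent area
raster slots in unchanged).

`groundwater_population()` converts rural and urban population rasters into
groundwater-consuming population via per-country usage rates. Three
estimators then bracket the population at risk:

* **high** — `sum(pop * p)`: every cell contributes its population weighted
  by its probability (a cell of 100 people at p = 0.47 counts 47);
  densely-populated low-hazard cells still accumulate, so this is an upper
  bracket.
* **low** — `sum(pop[p > 0.5])`: full population of cells above the
  crossover-level cutoff only; neglects near-threshold cells, a lower
  bracket.
* **hybrid** — `sum((pop * p)[p > 0.25])`: probability-weighted counting
  restricted to cells above *half* the crossover; the headline estimator,
  always ≤ high.

Cutoffs compare strictly (`>`), the hybrid cutoff is parameterized as
crossover/2 with 0.25 as the documented default, nodata hazard cells
contribute zero and are reported as uncovered population, and counts stay
real-valued until presentation. `aggregate_exposure()` produces the ranked
country table (hybrid with the low–high range) and continent totals with
affected-population percentages.

## The synthetic world

`synthetic_scenario()` fixes the study conditions; its defaults are the
reference conditions used by the test suite:

| parameter | default | rationale |
|---|---|---|
| grid | 200 × 200 planar cells | large enough for two-resolution bands and spatial structure, small enough to regenerate in seconds |
| covariates | 12 bands; even-numbered continuous bands stored at 4× coarser cells; last band binary categorical (a lithology-style indicator, thresholded at the 80th percentile of a smooth field) | mirrors a mixed ~1 km / ~250 m predictor stack with one categorical layer |
| random fields | white noise convolved with a truncated Gaussian kernel (correlation length = kernel SD = 10 cells), standardized | simple, dependency-light stationary fields |
| truth | `p = plogis(b0 + 4*cov1 - 3*cov2 + 2*cov3)`; intercept calibrated by bisection so the spatial mean is 0.102 | a strongly geogenic-controlled process: an oracle classifier on the informative covariates attains AUC ≈ 0.98, comfortably inside the generator's documented strong-signal regime (oracle AUC > 0.95); prevalence matches the ~10% exceedance share of large compilations |
| wells | 5000, uniform over cells; labels Bernoulli(p) | label noise is irreducible, as in reality |
| concentrations | lognormal(log 0.3, 0.8) truncated ≤ 1.5 for negatives; 1.5 + lognormal(log 0.8, 0.8) for positives | pooled median ≈ 0.3 mg/L, echoing the skewed shape of real compilations (documented, not asserted) |
| duplicates | 10% of wells with 2–3 replicate rows, concentration jittered on the same side of 1.5, identical coordinates | exercises deduplication |
| depths | 83% lognormal(log 70, 1.4) truncated to 0–600 m, rest uniform 600–3000 m, 10% missing | median ≈ 70 m and an ~83% shallow share, as in large well inventories |
| in-situ columns | `ec` monotone-increasing in the exceedance logit; `ca` V-shaped against it | exercises the association module's signed and non-monotone cases |
| population | log-Gaussian rural field plus sharp urban bumps; countries as meridional strips; rural usage U(0.3, 0.9), urban U(0.1, 0.6) | clustered, non-negative, zonally summable |

Everything derives deterministically from one master seed (per-purpose
streams are split off arithmetically), so identical scenarios are
bit-identical.

What the generator does **not** emulate: real covariate semantics (aridity,
evapotranspiration, pH), geodesic geometry and latitude-dependent cell
areas, preferential/clustered well placement, spatially correlated label
noise, and country-scale heterogeneity in measurement quality. Passing
tests therefore demonstrate that the machinery is correct and recovers a
known truth under realistic structure — not that any particular real-world
accuracy will be achieved.

## Association diagnostics

For any parameter (in-situ chemistry or a covariate),
`binned_association()` ranks the values into equal-count bins — bin count by
the Rice rule `ceiling(2 * n^(1/3))` (rounding up is this package's
convention; the rule avoids the over-smoothing of Sturges' rule at large n)
— computes the exceedance prevalence per bin, and reports Kendall's tau
(tau-b, tie-corrected; exact p-value for small untied bin counts, normal
approximation otherwise) between bin medians and prevalences. Bin sizes
differ by at most one; the size-weighted mean of bin prevalences
reconstructs the pooled prevalence exactly. `class_boxplots()` gives Tukey
five-number summaries per exceedance class (type-7 quantile hinges,
whiskers at the most extreme point within 1.5 IQR, outliers listed, both
conventions fixed for testability).

## Numerical choices and degenerate inputs

* Intercept calibration: bisection on `[-40, 40]` to `1e-6` in the mean
  probability (the mean is monotone in the intercept, so this is exact to
  tolerance).
* Equal-count binning puts the `n mod k` extra elements in the leading
  bins; ties may straddle bins (rank order, stable in input order).
* `stratified_split()` errors when a class has fewer than 2 rows; metrics
  with an absent class return `NA` with a flag rather than failing.
* Negative concentrations are rejected with a warning at deduplication.
* RFE removes `max(1, floor(0.2 p))` features, so it always terminates.
* Crossover threshold ties resolve to the midpoint of the tied thresholds.
* All seeds are kept below 2^31; every stochastic function takes or derives
  an explicit seed.

## Problem sizes used by the tests

Module tests run on a compact 60 × 60 / 8-covariate / 1200-well scenario.
The acceptance-style checks run the reference conditions — 200 × 200 grid,
12 covariates (3 informative), 5000 wells, 301 trees, 20 stratified 80/20
repetitions — replicated at three consecutive scenario seeds for the
crossover check, whose single-seed estimate has a standard deviation of
roughly 0.015; averaging three replicates tests the estimand rather than
one seed's draw. The end-to-end pipeline test uses a still smaller
configuration (`default_run_config()`) chosen to finish in seconds.

## Known limitations

* The forest's vote-fraction reading is miscalibrated for the minority
  class at desk-scale n (see above); use the default probability reading
  when downstream logic depends on the 0.5 operating point.
* Permutation importance splits credit between strongly correlated
  features; rankings between an informative group and noise are stable,
  individual values are not.
* The container is a planar in-memory grid with text (ESRI ASCII) I/O —
  adequate for the scales here; a geospatial raster backend would be needed
  for continental 250 m grids.
* Country-level usage rates are applied uniformly within a country; no
  sub-national variation.
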