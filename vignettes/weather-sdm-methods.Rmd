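---
title: "Methods: temporally explicit weather SDMs and the abundance linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporally explicit weather SDMs and the abundance linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(weatherSDM)
```

This vignette is the package's account of its own methods: the statistical
model, the choices we made where the design was genuinely open, the
assumptions behind the synthetic study system, and what the tests do and do
not demonstrate.

## 1. The modelling problem

We observe presence-only occurrence records of a focal species, each with a
month-year stamp, on a landscape covered by monthly weather grids, plus an
annual abundance index (AI) from a fixed panel of standardised count
transects. The question is temporal: did the *area of weather-suitable
habitat*, reconstructed month by month over decades, track the species'
abundance — and if the two decoupled, when?

The pipeline is: derive trailing-window climatic covariates; prepare
occurrences; build a bias-matched background; fit a maximum-entropy
presence–background model; project it monthly and binarise to core-habitat
area; then relate the area series to the AI with changepoint detection and
segmented regression.

## 2. Covariates

Eight covariates summarise a monthly window: annual precipitation,
wettest-quarter and driest-quarter precipitation, precipitation seasonality,
annual mean temperature, warmest-month maximum, coldest-month minimum, and
temperature seasonality. Conventions we fixed where the definitions are
loose:

* **Windows.** A record in month *t* uses the 12 or 36 months strictly
  preceding *t* — never the record's own month, and never a silently
  truncated window (a record too close to the grid start is excluded and
  logged). The two window lengths reflect an annual breeder (12 months:
  conditions since the last breeding opportunity) and cumulative or lagged
  effects over a ~3-year lifetime (36 months).
* **Quarters** are any 3 *consecutive* months inside the window, no
  wrap-around, so a 36-month window has 34 candidate quarters and its
  wettest quarter is a raw 3-month total, comparable with the 12-month
  version. `ann_prec` is annualised (`× 12/length`) so the two windows share
  units.
* **Seasonality** is the sample (n−1) coefficient of variation, on mm for
  precipitation and on kelvin for temperature. Kelvin avoids the sign and
  divide-by-zero pathologies of a Celsius mean near 0 °C. We do not add the
  conventional +1 mm offset to mean precipitation; with monthly means well
  above zero the offset is negligible, and omitting it keeps the definition
  self-contained. A window with zero total precipitation has seasonality 0
  by convention.
* **Climatology** covariates (the long-term "climate model" comparison)
  average each calendar month over a 30-year baseline (default 1976–2005)
  and then apply the same derivation to the 12-value climatology.

## 3. Occurrence preparation

Records with date accuracy worse than 1 month or location accuracy worse
than 10 km are dropped (bounds inclusive: a record *at* the bound stays, as
the exclusion rule is "worse than"). Within each species × month × year,
records within 5 km are collapsed: greedy single-linkage in input order —
a record joins the cluster of the first earlier record within the radius,
chains therefore merge, and each cluster is represented by its first-seen
record. Retained records are pairwise > 5 km apart, which makes the
operation idempotent. The clustering topology for chained records is not
uniquely determined by a radius rule; greedy-by-input-order is simple,
deterministic, and configurable (`radius`, distance metric: planar km on
synthetic grids, haversine on lon/lat).

## 4. Target-group background and the maxent model

The background is not uniform: 100,000 draws (with replacement) from the
empirical distribution of (location, year, month) triples of *all* species
recorded by the same survey methods, focal species included, weighted by
record multiplicity. Presence and background therefore share the survey
bias, and the model's contrasts isolate environment rather than effort. We
do not add presences to the background rows: the target group already
contains them as records.

Features are linear, quadratic and pairwise-product transforms (hinge and
threshold classes deliberately disabled, for smooth response curves),
min–max scaled to [0, 1] on the background; presence and projection features
reuse the background constants and clamp. Features of a constant covariate,
including its products, are dropped with a warning.

The coefficient vector maximises the L1-penalised mean presence
log-likelihood of the Gibbs distribution over the background (Section
"The model" of the README gives the formulas). Choices:

* **Penalty** `beta_j = beta_multiplier · s_j / sqrt(m)`, `s_j` the
  background standard deviation of feature *j*, `m` the presence count —
  the natural scale of the sampling noise in a feature's presence mean.
  The historical tool's per-feature-class tuned constants are not
  reproduced; `beta_multiplier` (default 1) is the single exposed knob.
* **Optimiser**: cyclic coordinate descent; each coordinate takes a
  one-dimensional Newton step soft-thresholded for the L1 penalty, with
  step-halving so the objective trace is monotone. Convergence is declared
  when a full sweep improves the objective by less than `tol` (default
  1e-7, tightened in tests comparing against a generic convex solver).
  Non-convergence is an error carrying the trace, never a silent result.
* **Logistic output** `e^H q / (1 + e^H q)`, with `H` the entropy of the
  fitted distribution over the training background: the standard monotone
  calibration that puts a "typical" background cell at 0.5.

Evaluation: AUC is the tie-aware Mann–Whitney probability; permutation
importance permutes one covariate across the pooled presence+background
rows (a single permutation by default, matching common practice;
`n_perm` raises stability), rebuilds that covariate's features, and
normalises the positive AUC drops to 100%. The 12- vs 36-month version of
each variable is chosen by the larger importance in a joint 16-covariate
fit; an exact tie keeps the 12-month version (shorter memory, more
parsimonious). Pairwise Pearson correlations above 0.85 among the final
covariates are flagged but nothing is dropped automatically — on a small
smooth island the surviving covariates are highly inter-correlated, and the
fit is regularised; the screen is a report for the analyst.

## 5. Projection, threshold, area

The final model is projected onto every month's covariate surfaces
(1950–2009 by default: 720 surfaces). The binarisation threshold equalises
*training* sensitivity and specificity: over candidate thresholds equal to
the observed scores, minimise |sens − spec|, ties resolved to the lowest
threshold. Monthly core-habitat area is the count of suitable cells times
cell area. The **annual** area carried into the abundance analysis is the
*mean* of the 12 monthly areas: the yearly min and max are reported
alongside, and the statistic is configurable, but the mean is the least
noisy single summary of "how much habitat that year offered". Cell area is
constant on the synthetic planar grid; geographic grids would weight by
`cos(latitude)`.

## 6. Abundance analysis

The AI for a span of years uses only transects counted in *every* year of
the span (the fixed panel; exclusions are logged). Changepoint detection is
at-most-one-change: the split maximising a criterion over all n−1
positions, the changepoint year being the **last year of the pre segment**.
The default criterion honours the distribution-free framing: the centred
rank CUSUM |Σ_{t≤k}(r_t − r̄)| normalised by √(k(n−k)), with significance
from permutation of the series (999 permutations, α = 0.05); a Gaussian
sum-of-squares reduction criterion is available as an alternative. The
area:AI ratio changepoint applies the same machinery to the per-year ratio;
zero-AI years are excluded with a warning (the ratio and the later log are
undefined).

Segmented regression fits area ~ ln(AI) by OLS separately on years up to
and including the changepoint and on the years after it; each segment needs
≥ 3 years, and a segment whose ln(AI) is constant returns NA statistics
with a warning rather than fabricating an F value. The natural log is used
(the base only rescales the slope). Regional 10-year change sums
per-transect differences of late vs early 3-year means within regions;
regions with no detections at all, or zero net change, are excluded with a
reason, and magnitudes are binned small < 3 ≤ medium ≤ 6 < large.

## 7. The synthetic island

The generator exists so that every stage can be tested against known truth;
its defaults *are* the study conditions of the package's acceptance tests.

* **Weather**: sinusoidal seasonal cycles (southern-hemisphere phase:
  January warmest, July coldest, winter-wet), linear spatial gradients, and
  one i.i.d. Gaussian interannual anomaly per year (additive ±0.8 °C;
  multiplicative log-normal, σ = 0.25, for precipitation) — the simplest
  structure that exercises all eight covariates. The spatial ranges are
  deliberately wide relative to the interannual anomalies (monthly
  precipitation ~30–200 mm west–east, annual means 7–17 °C), as on a real
  mountainous island: this matters, because if interannual variability
  rivals the spatial range, whole-island suitability slides through the
  binarisation threshold and the area series saturates at 0 or at the full
  island — a behaviour real systems with strong climatic gradients do not
  show.
* **Excursion**: inside the anomaly window (default 2001–2003) the three
  winter months' minima are raised (default +2 °C; applying the warming to
  the whole winter, not just the single coldest month, ensures the
  window-minimum covariate actually rises by the stated amount) and
  wettest-quarter precipitation is multiplied (default 1.5).
* **Truth**: a logistic function of the pipeline's own covariates —
  suitability declines with wettest-quarter precipitation (0.5 per 100 mm
  on the logit scale) and quadratically (0.09 per °C²) as the coldest-month
  minimum departs from a 0 °C optimum. With winter minima spanning about
  −4..+6 °C, the occupied range sits at or above the optimum, so both
  excursion levers are unfavourable where the species lives. The
  coefficients are set so the excursion roughly *halves* suitability rather
  than zeroing it — a partial dip, like published declines, keeps the
  area:AI ratio roughly stable through the excursion so that the ratio
  changepoint isolates the later count suppression rather than the weather
  dip itself.
* **Occurrences**: focal records sampled over cell-months ∝ truth × a
  smooth effort surface; two companion species ∝ effort alone — so
  companion density is independent of suitability given effort, exactly
  the property a target-group background needs.
* **Counts**: 30 regions × 5 transects (a ~150-transect panel, the scale of
  real statewide spotlight programmes), negative binomial (dispersion 2 —
  overdispersed, as real spotlight counts are) around `count_scale` (1.5)
  times mean truth over the transect's cells in a November–February survey
  season. From `suppression_start_year` (default 2004) the expectation is
  held at `suppression_factor` (0.4) times the transect's pre-suppression
  baseline, *decoupled from the weather* — emulating an abundance held down
  by something the weather model does not contain.
* **Scenario timing**: through the trailing windows, the 2001–2003
  excursion first reaches the November–February survey season in 2002 and
  releases after the 2004 season, so the "true" AI mean-shift year (last
  pre-shift year) is 2001, and the true area:AI decoupling year is 2003,
  the last year before suppression. The acceptance test asks both detected
  changepoints to fall within ±1 year of these, together with an
  in-excursion area dip and a significant-positive-pre /
  non-significant-post regression pair, in ≥ 80% of 50 replicate seeds.

What the generator does **not** emulate: topography and coastline,
spatially correlated anomaly fields (anomalies are island-wide), observer
effects and detection probability, range dynamics (dispersal, Allee
effects), or gradual trends in effort. Passing tests therefore demonstrate
that the *statistical machinery* recovers structure it is pointed at, not
that any real decline has a weather explanation.

## 8. Numerical and engineering choices

* Gridded data live in plain arrays inside a `climate_cube` list, with
  long-format CSV readers/writers for interchange; no binary raster
  dependencies.
* The vectorised covariate stack (rolling sums/extrema via `cumsum` and
  `embed`) is tested cell-by-cell against the scalar window path, which in
  turn is tested against a naive loop oracle.
* Log-sum-exp guards all normalisations; the fitted distribution must sum
  to 1 over the background to 1e-9 after every fit.
* Coordinate-descent curvature is floored at 1e-12; a coordinate step that
  cannot improve the objective after 40 halvings is skipped.
* Ties: changepoint split — earliest position; threshold — lowest
  candidate; window selection — 12-month version.
* All stochastic stages (generators, background, folds, permutations) take
  explicit seeds derived from one master seed; a rerun of a config is
  bit-identical.

## 9. Problem sizes

Default analysis scale, used by `scripts/acceptance.R`: 20 × 20 grid
(25 km² cells), weather 1947–2009, 1500 focal + 6500 companion records,
8000 background points, 720 monthly projections, a 20-year abundance panel;
about 2 minutes on one CPU. The replicate-seed structural test runs 50
pipeline replicates at the same grid and panel but a 22-year weather
history, 400 presences and 1500 background points, 12-month windows only.
These sizes are the package's standard desk-scale configuration; all
contracts are size-free and the same code runs larger grids unchanged.

## 10. Known limitations

* The maxent implementation targets the stated convex objective; it does
  not reproduce the historical tool's tuned per-class regularisation, so
  coefficient-level equality with that tool is out of scope (distributional
  agreement on synthetic data is the contract).
* Permutation importance with one permutation is noisy by construction;
  window selection inherits that noise (raise `n_perm` for stability).
* The at-most-one-change detector assumes a single mean shift; a gradual
  multi-year transition makes "the" changepoint year ambiguous to ±1, which
  is why the structural test uses a ±1 tolerance.
* The equal sensitivity/specificity threshold is computed on training data,
  as is conventional, and is optimistic to the same degree as the training
  AUC.
* Ratio and regression stages exclude zero-AI years; a species driven to
  zero counts for much of a series needs a different abundance model
  (e.g. hurdle counts), not this ratio analysis.
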