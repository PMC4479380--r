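# weatherSDM

Temporally explicit, weather-based species distribution modelling, with a
downstream abundance–distribution analysis.

Classic climatic SDMs relate occurrences to long-term climate means and
produce a static suitability map. For short-lived species whose numbers
respond to the weather they actually experienced, that throws away the
signal: a run of bad years can crash a population that the 30-year
climatology says should be fine. `weatherSDM` instead stamps every occurrence
record with covariates computed over the 12 and 36 months *immediately
preceding* the record's month, fits a presence–background model to those
temporally explicit covariates, and then projects the fitted model onto every
month of a multi-decade weather history. The result is a monthly time series
of habitat suitability — and of core-habitat area — that can be compared
against an independent abundance index to ask when, and whether, abundance
decoupled from the weather.

The package is aimed at quantitative ecologists diagnosing declines of
range-restricted species monitored by standardised counts (spotlight
transects, trap indices) where gridded monthly weather is available.

## The model

**Covariates.** From monthly precipitation and temperature grids, eight
bioclimatic covariates per trailing window: annual precipitation,
precipitation of the wettest and driest quarter (any 3 consecutive months in
the window), precipitation seasonality (CV, %), annual mean temperature,
maximum temperature of the warmest month, minimum temperature of the coldest
month, and temperature seasonality (CV on kelvin).

**Maximum entropy.** With features f(x) (linear, quadratic and pairwise
products, min–max scaled on the background), the model is the Gibbs
distribution over the background sample B

    q_lambda(x) = exp(lambda . f(x)) / sum_{x' in B} exp(lambda . f(x'))

with lambda maximising the L1-penalised mean presence log-likelihood

    (1/m) sum_i log q_lambda(x_i) − sum_j beta_j |lambda_j|,
    beta_j = beta_multiplier · s_j / sqrt(m).

Fitting is cyclic coordinate descent with soft-thresholding and a guaranteed
monotone objective. Suitability is reported through the entropy-calibrated
logistic transform `e^H q / (1 + e^H q)`, H the entropy of q over the
background. Sampling bias is absorbed by a *target-group background*: 100,000
points drawn from the (location, year, month) triples of all species recorded
by the same survey methods, weighted by record multiplicity.

**Downstream.** Monthly projections are binarised at the equal training
sensitivity/specificity threshold; suitable cells × cell area give the
core-habitat area series. An abundance index (total annual counts over a
fixed transect panel) is compared with the area series via at-most-one-change
changepoint detection (rank CUSUM, permutation significance) on the index and
on the area:index ratio, and by separate OLS regressions of area on ln(AI)
before and after the detected changepoint.

Because the motivating study's occurrence, weather and count data are not
redistributable, the package ships a synthetic island generator
(`gen_weather()`, `truth_surface()`, `gen_occurrences()`, `gen_transects()`)
that reproduces the statistical structure of the system — spatial climate
gradients, seasonal cycles, interannual anomalies, a multi-year unfavourable
excursion, shared sampling bias, and optional post-excursion count
suppression — so every stage is testable against known truth.

## Worked example

```r
library(weatherSDM)

cfg <- run_config(
  synth = synthetic_config(seed = 1),   # 20 x 20 island, 1947-2009
  seed = 1, n_focal = 1500, n_target_group = 6500,
  background_n = 8000, project_years = 1950:2009,
  climate_model = TRUE)
bundle <- run_full_model(cfg)
bundle
#> model_bundle
#>   presences: 1403, background: 8000, covariates: ann_prec_12m, ...
#>   CV AUC 0.644 +/- 0.011, threshold 0.504
#>   AI changepoint year 2001, ratio changepoint year 2003
bundle$changepoint_ai
#> changepoint after position 12 (year 2001): mean 63.333 +/- 6.367 -> 19.375 +/- 2.712
#>   distribution_free statistic 4.797, permutation p = 0.0010 (significant)
bundle$segments$pre[c("slope", "r_squared", "p_value")]
#> $slope      [1] 1173.58
#> $r_squared  [1] 0.7574
#> $p_value    [1] 5.17e-05
bundle$segments$post[c("r_squared", "p_value")]
#> $r_squared  [1] 0.0688
#> $p_value    [1] 0.6156
```

Read: cross-validated discrimination is well above random (AUC 0.64 against
a bias-matched background that deliberately removes most of the easy
spatial signal); the abundance index shifts from a mean of 63 to 19
sightings after 2001, when the island's simulated 2001–2003 unfavourable
excursion reaches the survey seasons; the area:AI ratio decouples after 2003
when count suppression begins; suitable area explains ~76% of ln(AI)
variance before the decoupling and ~7% (n.s.) after — the structure the
method is designed to expose.

`write_bundle(bundle, "out/")` exports the prepared records, area series,
abundance index, regional-change table and a JSON summary.
`run_independent_model(cfg, full = bundle)` repeats everything with
spotlight-source records excluded from both the presences and the
target group, for an area series independent of the count data.

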