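---
title: "Forecasting higher-than-expected daily deaths with quantile regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting higher-than-expected daily deaths with quantile regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsurveil)
```

## The problem

Classical daily-mortality models target the conditional *mean* number of
deaths.  For health-system capacity planning and syndromic surveillance the
more useful quantity is often an upper conditional quantile — the number of
deaths that will not be exceeded on, say, 90% of days like this one.  A day
whose count lies above that threshold is "higher than expected"; sustained
runs of such days can signal an emerging exposure.  Crucially, the
conditional threshold moves with the season: a count that is unremarkable
in January can be highly unusual in July, and a fixed annual threshold
misses exactly those summer signals.

`qrsurveil` models the conditional `tau`-quantile (default `tau = 0.9`) of
a daily respiratory death count as a linear function of seasonal, temporal,
and lagged environmental predictors, fitted by quantile regression, and
scores both in-sample *prediction* and genuine out-of-sample *forecasting*.

## The model and its estimator

For coefficients $\beta$ and day-$i$ predictors $x_i$, the fitted
conditional quantile is $q_i = x_i'\beta$, estimated by minimizing the
weighted sum of absolute deviations (WSAD; the check or pinball loss)

$$ \mathrm{WSAD}(\beta) \;=\; (1-\tau)\sum_{y_i < q_i} |y_i - q_i|
   \;+\; \tau\sum_{y_i > q_i} |y_i - q_i| , $$

where observations sitting exactly on the fit contribute nothing.  This is
a linear program, and `qr_fit()` solves it *exactly* with a specialized
exchange (vertex-pivoting simplex) algorithm rather than a smoothed
approximation:

* every basic solution interpolates exactly $p$ observations, so solutions
  are reproducible vertices of the LP;
* non-interpolated observations with zero residual — ubiquitous with tied
  integer counts — carry a persistent side label, and zero-length pivots
  walk through such degenerate vertices; termination is the standard
  simplex optimality certificate, so heavy ties cannot cause a premature
  stop.  A Bland-style lowest-index rule engages only after a long run of
  degenerate pivots, as an anti-cycling safeguard;
* on flat optima (e.g. intercept-only fits with $n\tau$ integer) the
  reported solution is the *lower* vertex; `unconditional_quantile()`
  implements the same convention as an order statistic
  (`ceiling(n * tau)`-th, or the `n * tau`-th when $n\tau$ is an integer)
  and is tested to coincide with the intercept-only LP fit.

Numerical tolerances: directional-derivative optimality `1e-9`; residuals
within `1e-9 * max(1, max|y|)` of zero are treated as on-fit; the rank of
the design is checked by column-pivoted QR at tolerance `1e-10`, and
collinear columns are reported by name rather than silently dropped.

Every fit is checked in the test suite against the quantile *sign
property* of LP optimality — at most $n\tau$ observations strictly below
the fit and at most $n(1-\tau)$ strictly above — and against two
independent oracles: the Barrodale–Roberts solver in `quantreg`, and
exhaustive enumeration of all interpolating vertices for tiny problems.

### Counts and jittering

Quantile regression with integer counts is slightly non-standard because
the loss is piecewise linear with kinks at the data.  A common device is to
"jitter" the counts with small additive uniform noise before fitting.
`qr_fit(..., jitter = list(amount = 0.1, seed = ...))` supports this
(uniform on ±`amount`, applied to the response only, with its own seeded
RNG stream); the default is **off**, and an acceptance test verifies that
R1 moves by less than 0.01 when jittering at ±0.1 — the model comparison
does not depend on the device.

## Features

* **Cosinor terms** (`make_cosinor`): paired sine/cosine columns with
  periods 365.25 and 182.625 days — the linear-in-parameters form of a
  cosinor, able to represent any amplitude and phase of a yearly plus
  half-yearly cycle.  Time is counted in whole days from a single origin
  (the first day of the *full* dataset), so in- and out-sample designs
  share one phase convention.
* **Day-of-week indicators** (`make_dow_dummies`): six 0/1 columns with a
  fixed Sunday reference (the choice moves coefficients, not fits).  The
  weekday is computed arithmetically from the date, independent of locale.
* **Lags** (`make_lag`): the day-$t$ value of a lag-$k$ column is the
  covariate at day $t-k$; the first $k$ days become missing and missing
  inputs propagate.
* **Trailing moving averages** (`make_moving_average`): mean of the
  current and previous `window - 1` days, missing if any window day is
  missing.  A trailing window is used because a forecast cannot read
  future covariate values; centred alternatives would leak.

`assemble_design()` builds the four model structures — M1 intercept only,
M2 seasonal/temporal (11 columns), M3 = M2 + one selected lag per
covariate, M4 = M2 + 7-day moving averages — and applies complete-case
filtering per model, reporting how many days were dropped.  Lags make the
row sets differ slightly across models; the comparison table therefore
reports per-model day counts rather than pretending to a common basis.

## Lag selection

For each covariate, `select_lag()` fits one screening model per candidate
lag (1–7 days) and keeps the lag with the smallest WSAD.  Two choices here
were genuinely open:

* **Base terms.** The screening models include the cosinor and day-of-week
  terms by default (`base_terms = TRUE`), so a lag is judged on signal
  *beyond* seasonality.  Without them, every lag of a seasonal covariate
  scores almost identically (a sinusoid shifted by a few days is nearly
  the same sinusoid) and selection degenerates to noise.  The flag exposes
  the alternative.
* **Common rows.** WSAD values computed on different day sets are not
  comparable, so all candidate fits for one covariate are restricted to
  the complete cases common to *every* candidate lag.

Ties break toward the smallest lag: the more parsimonious choice, and the
one available earliest when forecasting.

## Evaluation

`split_sample()` divides the series at a cutoff date into a development
half and a cross-validation half.  `evaluate_models()` fits each structure
on the development half only, then applies the frozen coefficients to the
later half; for the unconditional model the forecast is the constant
in-sample quantile, a deliberate convention — using the out-sample's own
quantile would not be a forecast.  Designs are assembled on the full
series before splitting, so lagged predictors for the first out-sample
days read the last in-sample covariate values, exactly as a live
forecaster could.

Fit is summarized by the quantile coefficient of determination

$$ R_1 = 1 - \frac{\mathrm{WSAD}_{\text{model}}}
                  {\mathrm{WSAD}_{\text{unconditional}}} , $$

the proportionate reduction in check loss over the intercept-only model.
In-sample $R_1$ is non-negative for any model nesting the intercept;
out-of-sample $R_1$ can be negative and is never clamped.  Values are
reported to 3 decimals in outputs, full precision internally.

`flag_exceedance()` classifies each day against the constant unconditional
threshold and the day's conditional quantile, with strict inequality for
exceedance (a count equal to its quantile carries zero check loss, so it
is "typical").  The four categories partition the days; the discordant
ones are the scientifically interesting sets — winter days whose high
counts the season fully explains, and summer days with absolutely modest
counts that are nonetheless unusual for their season.

## The synthetic generator

No real city series ships with the package; `simulate_daily_series()`
generates one with known ground truth so that every downstream stage is
testable.  It emulates the structure of the NMMAPS New York City
respiratory-mortality extract:

* negative-binomial daily counts (size 50 by default — mild
  overdispersion; Poisson is the large-size limit) whose log mean carries
  a winter-peaking yearly cosinor (cos amplitude 0.18, sin 0.03), a small
  half-yearly term (0.03), and day-of-week effects of a percent or two;
* a baseline calibrated so the designed mean — the average of
  `exp(log mean)` over the simulated days — equals 70830/5114 ≈ 13.85
  deaths/day over 5114 days from 1987-01-01; under these defaults the
  marginal 90th percentile is 20, matching the in-sample unconditional
  threshold of about 20 deaths/day that the conditional models improve
  upon;
* covariates simulated as seasonal sinusoids plus AR(1) anomalies with
  magnitudes loosely matching NYC daily data (temperature ~55 ± 20 °F
  peaking in July, ozone peaking in summer, combustion products in
  winter), and optional lagged log-linear effects.  Effects multiply the
  covariate's *anomaly* from its mean level, so switching an effect on
  does not shift the series' designed scale, while the implied true model
  stays exactly linear in the covariate (the centering constant is
  absorbed by the intercept).  The default lag pattern is 1 day for CO,
  NO2, O3 and dew point and 3 days for temperature and SO2, with all
  effect sizes zero unless set;
* completely-at-random missingness at a configurable per-cell rate (the
  real data's missingness mechanism is unknown; MCAR is the neutral
  choice).

Ground truth (the full log mean, the complete pre-missingness series, and
the exact per-day negative-binomial quantile) is returned in a sidecar so
recovery tests never re-derive it from the data.

For effect-size-dependent tests the package's study condition is a lag-3
temperature effect of −0.02 per °F: with a temperature SD near 15 °F this
moves the expected count by roughly one count-noise standard deviation
(√(μ + μ²/50) ≈ 4.2 at μ ≈ 13.9), the magnitude at which a lag should be
clearly identifiable in 2500 days of data.

What the generator does *not* reproduce: heat-wave extremes and other
non-sinusoidal seasonal shapes, influenza epidemics, holiday artifacts,
long-memory trends, measurement changes, and covariate missingness that
tracks the pollution level itself.  Tests passing on this generator
demonstrate that the machinery recovers known structure under realistic
noise — not that any particular city's mortality obeys the model.

## Problem sizes used in the test battery

Simulation-based checks use 2500-day series (about half the NYC study
length) with the in/out split at day 1250, 20–50 replicates per claim, and
a 5000-day design for coefficient-recovery checks; these sizes give the
Monte-Carlo margins quoted in the tests while keeping the battery quick to
run.

## Known limitations

* Single-city, single-outcome design; no spatial pooling.
* One lag per covariate, selected marginally — no distributed-lag or
  interaction structures.
* No uncertainty quantification for coefficients or forecasts: the method
  compares models by held-out loss, and coefficient inference is
  deliberately out of scope.
* Quantile crossing is not an issue at a single `tau`, but nothing
  constrains fits run at several levels to be mutually consistent.
* The exchange solver is exact but dense; series of a few tens of
  thousands of days remain comfortable, millions would not be.

## A minimal run

```{r, eval = FALSE}
ce <- default_covariate_effects()
ce$tmean$effect <- -0.02          # cold snaps raise deaths three days on
cfg <- synthetic_config(n_days = 5114, covariate_effects = ce, seed = 42)
res <- run_pipeline(run_config(synthetic = cfg, seed = 42,
                               cutoff = as.Date("1993-12-31"),
                               output_dir = "run1"))
res$comparison
table(res$exceedance$flag)
```
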