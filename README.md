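# qrsurveil

Quantile-regression prediction and forecasting of **higher-than-expected
daily health event counts**, for epidemiologists and health-services
analysts working with daily mortality/morbidity time series of the NMMAPS
kind (daily death counts plus weather and air-quality covariates).

Instead of modelling the expected number of deaths, `qrsurveil` models an
upper conditional quantile — by default the 90th percentile — of the daily
respiratory death count. Days strictly above the fitted quantile are
"unusual"; because the threshold is conditional on season, day of week,
and recent weather/air quality, it flags summer days with absolutely
modest but seasonally surprising counts, and excuses winter days whose
high counts the season fully explains.

## The method

A linear conditional-quantile model `q_i = x_i'β` is fitted at level τ by
exact minimization of the weighted sum of absolute deviations (check /
pinball loss)

```
WSAD(β) = (1 − τ) · Σ_{y_i < q_i} |y_i − q_i|  +  τ · Σ_{y_i > q_i} |y_i − q_i|
```

via a specialized exchange (vertex simplex) algorithm with explicit
degeneracy handling for tied integer counts (`qr_fit()`). Four model
structures are compared:

| model | predictors |
|---|---|
| M1 | intercept only (unconditional quantile) |
| M2 | yearly + half-yearly cosinor, day-of-week indicators |
| M3 | M2 + one selected lag (1–7 d) per weather/air-quality covariate |
| M4 | M2 + 7-day trailing moving averages of the covariates |

Lags are chosen per covariate by screening each candidate lag's WSAD on a
common row set (`select_lag()`). Models are fitted on the earlier half of
the series (prediction) and applied with frozen coefficients to the later
half (forecasting); both are scored by the quantile coefficient of
determination

```
R1 = 1 − WSAD_model / WSAD_unconditional ,
```

the proportionate reduction in check loss over the intercept-only model
(`evaluate_models()`). Finally each day is classified as
typical/unusual under the unconditional versus the conditional threshold
(`flag_exceedance()`).

A ground-truth-emitting synthetic generator (`simulate_daily_series()`)
reproduces the structure of the NYC 1987–2000 series (≈13.85 deaths/day
designed mean, winter-peaking seasonality, negative-binomial
overdispersion, seasonal covariates with lagged effects, optional
missingness), so the entire pipeline is testable without any data
download.

## Worked example

```r
library(qrsurveil)

ce <- default_covariate_effects()
ce$tmean$effect <- -0.02           # cold snaps raise deaths three days on
cfg <- synthetic_config(n_days = 5114, covariate_effects = ce, seed = 42)
sim <- simulate_daily_series(cfg)
s   <- sim$series

halves <- split_sample(s, as.Date("1993-12-31"))
sel <- select_all_lags(halves$in_sample, origin = s$date[1])
sel
#>   tmean  -> lag 3 (WSAD 2075.47)
#>   dptp   -> lag 5 (WSAD 2207.85)
#>   o3     -> lag 2 (WSAD 2212.67)
#>   so2    -> lag 1 (WSAD 2211.65)
#>   no2    -> lag 3 (WSAD 2210.77)
#>   co     -> lag 7 (WSAD 2199.55)

specs <- list(model_spec("M1_unconditional"), model_spec("M2_seasonal"),
              model_spec("M3_seasonal_lags", lag_map = lag_map(sel)),
              model_spec("M4_seasonal_ma"))
cmp <- evaluate_models(s, specs, tau = 0.9, cutoff = as.Date("1993-12-31"))
cmp
#> Model comparison at tau = 0.9 (cutoff 1993-12-31)
#>   Prediction (in-sample)
#>     M1_unconditional   n= 2557  WSAD=   4032.3  R1=0.000
#>     M2_seasonal        n= 2557  WSAD=   2234.9  R1=0.446
#>     M3_seasonal_lags   n= 2550  WSAD=   2062.8  R1=0.488
#>     M4_seasonal_ma     n= 2551  WSAD=   2150.9  R1=0.467
#>   Forecasting (out-sample)
#>     M1_unconditional   n= 2557  WSAD=   4101.6  R1=0.000
#>     M2_seasonal        n= 2557  WSAD=   2313.3  R1=0.436
#>     M3_seasonal_lags   n= 2557  WSAD=   2203.3  R1=0.463
#>     M4_seasonal_ma     n= 2557  WSAD=   2258.4  R1=0.449

table(exceedance_table(cmp)$flag)
#>        typical_both        unusual_both unusual_uncond_only   unusual_cond_only
#>                4287                 195                 284                 341
```

The generator's true temperature effect sits at lag 3, and the screening
step recovers it; the other covariates carry no true effect, so their
selected lags are noise. The lagged-covariate model M3 reduces the check
loss by 48.8% in-sample, and — the pattern that matters for surveillance —
forecasts the held-out years better than the purely seasonal model
(out-sample R1 0.463 vs 0.436, with the moving-average model in between).
The 341 `unusual_cond_only` days are counts an annual threshold would
never flag but which are high *for their season*; the 284
`unusual_uncond_only` days are high counts the season fully explains.

The same analysis runs from the shell:

```sh
Rscript inst/cli/qrsurveil.R run --synthetic --n-days 5114 --seed 42 --out run1
Rscript inst/cli/qrsurveil.R report --out run1
```

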