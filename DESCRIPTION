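Package: qrsurveil
Title: Quantile-Regression Forecasting of Higher-Than-Expected Daily
    Health Event Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts and forecasts the upper conditional quantile
    (by default the 90th percentile) of daily respiratory death counts
    from seasonal, temporal, weather and air-quality predictors.
    Provides an exact check-loss (pinball) minimizer for linear
    conditional-quantile models, cosinor and day-of-week feature
    construction, per-covariate selection of distributed lags by the
    weighted sum of absolute deviations, in-sample/out-of-sample
    cross-validated comparison of four model structures scored by the
    R1 coefficient of determination, exceedance re-classification of
    days against unconditional versus conditional thresholds, a
    ground-truth-emitting synthetic data generator emulating the NMMAPS
    daily series structure, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    optparse
Config/testthat/edition: 3
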