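test_that("split_sample partitions the series at the cutoff date", {
  s <- toy_series(365, start = as.Date("1987-01-01"))
  halves <- split_sample(s, as.Date("1987-06-30"))
  expect_equal(max(halves$in_sample$date), as.Date("1987-06-30"))
  expect_equal(min(halves$out_sample$date), as.Date("1987-07-01"))
  expect_equal(nrow(halves$in_sample) + nrow(halves$out_sample), nrow(s))
  expect_length(intersect(halves$in_sample$date, halves$out_sample$date), 0)
  expect_error(split_sample(s, max(s$date)), "strictly inside")
  expect_error(split_sample(s, as.Date("1800-01-01")), "strictly inside")
})

test_that("r1 is the proportionate WSAD reduction", {
  expect_equal(round(r1(1882.5, 2328.2), 3), 0.191)
  expect_equal(round(r1(2039.7, 2529.5), 3), 0.194)
  expect_equal(r1(123.4, 123.4), 0)
  expect_error(r1(1, 0), "wsad_null")
  expect_error(r1(-1, 10), "wsad_model")
})

test_that("evaluate_models scores prediction and forecasting coherently", {
  sim <- simulate_daily_series(synthetic_config(n_days = 1400, seed = 6))
  s <- sim$series
  cutoff <- s$date[700]
  specs <- list(model_spec("M1_unconditional"), model_spec("M2_seasonal"))
  cmp <- evaluate_models(s, specs, tau = 0.9, cutoff = cutoff)
  df <- as.data.frame(cmp)
  # M1's R1 is identically zero in both samples
  expect_equal(df$r1[df$model == "M1_unconditional"], c(0, 0))
  # R1 identity holds exactly per sample
  for (smp in c("in", "out")) {
    null_w <- df$wsad[df$model == "M1_unconditional" & df$sample == smp]
    for (m in df$model) {
      w <- df$wsad[df$model == m & df$sample == smp]
      expect_equal(df$r1[df$model == m & df$sample == smp], 1 - w / null_w,
                   tolerance = 1e-12)
    }
  }
  # strong seasonality: the seasonal model must improve on the constant
  expect_gt(df$r1[df$model == "M2_seasonal" & df$sample == "in"], 0)
  # M1 forecast is the frozen in-sample constant
  preds <- attr(cmp, "predictions")
  expect_equal(unique(preds$M1_unconditional$out_sample$predicted),
               unname(attr(cmp, "fits")$M1_unconditional$coefficients[1]))
  # stored predictions regenerate the tabled WSADs exactly
  for (m in df$model) {
    for (smp in c("in", "out")) {
      pp <- preds[[m]][[if (smp == "in") "in_sample" else "out_sample"]]
      expect_equal(wsad_loss(pp$deaths, pp$predicted, 0.9),
                   df$wsad[df$model == m & df$sample == smp],
                   tolerance = 1e-9)
    }
  }
  expect_error(evaluate_models(s, list(model_spec("M2_seasonal")),
                               cutoff = cutoff),
               "M1_unconditional")
})

test_that("in-sample R1 of models nesting the intercept is non-negative", {
  sim <- simulate_daily_series(synthetic_config(n_days = 1000, seed = 14))
  cmp <- evaluate_models(sim$series,
                         list(model_spec("M1_unconditional"),
                              model_spec("M2_seasonal"),
                              model_spec("M4_seasonal_ma")),
                         tau = 0.9, cutoff = sim$series$date[500])
  df <- as.data.frame(cmp)
  expect_true(all(df$r1[df$sample == "in"] >= -1e-10))
})

test_that("about 10 percent of in-sample days exceed the conditional fit", {
  sim <- simulate_daily_series(synthetic_config(n_days = 2500, seed = 18))
  s <- sim$series
  cmp <- evaluate_models(s, list(model_spec("M1_unconditional"),
                                 model_spec("M2_seasonal")),
                         tau = 0.9, cutoff = s$date[2000])
  pp <- attr(cmp, "predictions")$M2_seasonal$in_sample
  frac <- mean(pp$deaths > pp$predicted)
  n <- nrow(pp)
  # binomial 99% bounds around 0.10 (discrete counts put mass at the
  # threshold, so exceedance can only fall below tau, never above)
  expect_lt(frac, 0.10 + 2.58 * sqrt(0.1 * 0.9 / n))
  expect_gt(frac, 0.10 - 3 * 2.58 * sqrt(0.1 * 0.9 / n))
})

test_that("exceedance flags follow the threshold semantics and partition", {
  expect_equal(as.character(flag_exceedance(25, 20.2, 30)),
               "unusual_uncond_only")
  expect_equal(as.character(flag_exceedance(15, 20.2, 12)),
               "unusual_cond_only")
  expect_equal(as.character(flag_exceedance(10, 20.2, 12)), "typical_both")
  expect_equal(as.character(flag_exceedance(35, 20.2, 30)), "unusual_both")
  # equality is typical: zero check-loss weight at the threshold
  expect_equal(as.character(flag_exceedance(20, 20, 25)), "typical_both")
  set.seed(30)
  y <- rpois(500, 14)
  qc <- rnorm(500, 20, 3)
  fl <- flag_exceedance(y, 20.2, qc)
  expect_false(anyNA(fl))
  expect_equal(sum(table(fl)), 500)  # exhaustive and mutually exclusive
  agree <- (y > 20.2) == (y > qc)
  expect_equal(sum(fl %in% c("typical_both", "unusual_both")), sum(agree))
  expect_error(flag_exceedance(1:3, 20, 1:2), "matching lengths")
})

test_that("exceedance_table classifies every scored day of a comparison", {
  sim <- simulate_daily_series(synthetic_config(n_days = 800, seed = 21))
  s <- sim$series
  cmp <- evaluate_models(s, list(model_spec("M1_unconditional"),
                                 model_spec("M2_seasonal")),
                         tau = 0.9, cutoff = s$date[400])
  tab <- exceedance_table(cmp, model = "M2_seasonal")
  expect_equal(nrow(tab), 800)
  expect_true(all(levels(tab$flag) == c("typical_both", "unusual_both",
                                        "unusual_uncond_only",
                                        "unusual_cond_only")))
  expect_error(exceedance_table(cmp, model = "M3_seasonal_lags"),
               "not present")
})
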