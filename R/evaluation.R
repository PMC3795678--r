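#' Split a daily series into development and cross-validation halves
#'
#' @param series a \code{daily_series}.
#' @param cutoff a date strictly inside the series' date range: days at or
#'   before it form the in-sample (development) set, days after it the
#'   out-sample (forecast cross-validation) set.
#' @return List with elements \code{in_sample} and \code{out_sample}, both
#'   \code{daily_series}; no day is lost or duplicated.
#' @export
split_sample <- function(series, cutoff) {
  series <- as_daily_series(series)
  cutoff <- as.Date(cutoff)
  if (length(cutoff) != 1L || is.na(cutoff)) {
    stop("`cutoff` must be a single date", call. = FALSE)
  }
  rng <- range(series$date)
  if (cutoff < rng[1L] || cutoff >= rng[2L]) {
    stop("`cutoff` (", format(cutoff),
         ") must lie strictly inside the date range ", format(rng[1L]),
         " .. ", format(rng[2L]), call. = FALSE)
  }
  inside <- series$date <= cutoff
  list(in_sample = series[inside, , drop = FALSE],
       out_sample = series[!inside, , drop = FALSE])
}

#' Coefficient of determination for quantile models (R1)
#'
#' The proportionate reduction in the weighted sum of absolute deviations
#' achieved by a conditional model over the unconditional (intercept-only)
#' model: \code{1 - wsad_model / wsad_null}.  It plays the role R-squared
#' plays for least squares, but on the check-loss scale; out-of-sample
#' values can be negative and are reported as such.
#'
#' @param wsad_model criterion value of the conditional model (>= 0).
#' @param wsad_null criterion value of the unconditional model (> 0).
#' @return A single number, at most 1.
#' @examples
#' r1(1882.5, 2328.2)  # 0.191 to 3 decimals
#' @export
r1 <- function(wsad_model, wsad_null) {
  if (!is.numeric(wsad_null) || length(wsad_null) != 1L ||
      is.na(wsad_null) || wsad_null <= 0) {
    stop("`wsad_null` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(wsad_model) || length(wsad_model) != 1L ||
      is.na(wsad_model) || wsad_model < 0) {
    stop("`wsad_model` must be a single non-negative number", call. = FALSE)
  }
  1 - wsad_model / wsad_null
}

#' Fit, predict, and forecast the four model structures
#'
#' Fits every supplied model specification on the in-sample days only,
#' scores the training fit (prediction), then applies the frozen
#' coefficients to the out-sample days (forecasting) — for the
#' unconditional model the forecast is the constant in-sample quantile.
#' Designs are assembled on the full series with a shared time origin
#' before splitting, so lagged and moving-average predictors for the first
#' out-sample days draw on the late in-sample covariate values, exactly as
#' a real forecaster could.  Each model keeps its own complete-case rows;
#' the day counts are reported so the differing row sets stay visible.
#'
#' @param series a \code{daily_series}.
#' @param specs list of \code{\link{model_spec}}s; must include
#'   \code{M1_unconditional}, the denominator of every R1.
#' @param tau quantile level (default 0.9).
#' @param cutoff in-/out-sample split date (see \code{\link{split_sample}}).
#' @param origin cosinor time origin; defaults to the series' first date.
#' @param dow_reference reference weekday.
#' @param jitter optional jitter settings passed to \code{\link{qr_fit}}.
#' @return An object of class \code{comparison_table}: data.frame with one
#'   row per model x sample (\code{model}, \code{sample}, \code{n_days},
#'   \code{wsad}, \code{r1}), carrying the fits and per-day predictions as
#'   attributes \code{fits} and \code{predictions}.
#' @export
evaluate_models <- function(series, specs, tau = 0.9, cutoff,
                            origin = NULL, dow_reference = "sun",
                            jitter = NULL) {
  series <- as_daily_series(series)
  check_tau(tau)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  spec_names <- vapply(specs, function(s) s$name, character(1))
  if (!"M1_unconditional" %in% spec_names) {
    stop("`specs` must include M1_unconditional (the R1 denominator)",
         call. = FALSE)
  }
  if (anyDuplicated(spec_names)) {
    stop("duplicate model specs: ",
         paste(spec_names[duplicated(spec_names)], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(origin)) origin <- series$date[1L]
  cutoff <- as.Date(cutoff)

  rows <- list()
  fits <- list()
  preds <- list()
  for (spec in specs) {
    full <- assemble_design(series, spec, origin = origin,
                            dow_reference = dow_reference)
    inside <- full$dates <= cutoff
    if (sum(inside) == 0L || sum(!inside) == 0L) {
      stop("model ", spec$name,
           ": the split leaves an empty in- or out-sample", call. = FALSE)
    }
    d_in <- list(dates = full$dates[inside],
                 X = full$X[inside, , drop = FALSE],
                 y = full$y[inside])
    d_out <- list(dates = full$dates[!inside],
                  X = full$X[!inside, , drop = FALSE],
                  y = full$y[!inside])
    fit <- tryCatch(qr_fit(d_in, tau = tau, jitter = jitter),
                    error = function(e) {
                      stop("fitting ", spec$name, " failed: ",
                           conditionMessage(e), call. = FALSE)
                    })
    pred_out <- drop(d_out$X %*% fit$coefficients)
    rows[[spec$name]] <- data.frame(
      model = spec$name,
      sample = c("in", "out"),
      n_days = c(length(d_in$y), length(d_out$y)),
      wsad = c(fit$train_wsad, wsad_loss(d_out$y, pred_out, tau)))
    fits[[spec$name]] <- fit
    preds[[spec$name]] <- list(
      in_sample = data.frame(date = d_in$dates, deaths = d_in$y,
                             predicted = fit$fitted),
      out_sample = data.frame(date = d_out$dates, deaths = d_out$y,
                              predicted = pred_out))
  }

  tab <- do.call(rbind, rows[spec_names])
  null_wsad <- tab$wsad[tab$model == "M1_unconditional"]
  names(null_wsad) <- tab$sample[tab$model == "M1_unconditional"]
  tab$r1 <- mapply(function(w, s) r1(w, null_wsad[[s]]),
                   tab$wsad, tab$sample)
  rownames(tab) <- NULL
  structure(tab, class = c("comparison_table", "data.frame"),
            fits = fits, predictions = preds, tau = tau, cutoff = cutoff)
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison at tau = %g (cutoff %s)\n",
              attr(x, "tau"), format(attr(x, "cutoff"))))
  df <- as.data.frame(x)
  for (s in c("in", "out")) {
    part <- df[df$sample == s, ]
    cat(if (s == "in") "  Prediction (in-sample)\n"
        else "  Forecasting (out-sample)\n")
    for (i in seq_len(nrow(part))) {
      cat(sprintf("    %-18s n=%5d  WSAD=%9.1f  R1=%.3f\n",
                  part$model[i], part$n_days[i], part$wsad[i],
                  round(part$r1[i], digits)))
    }
  }
  invisible(x)
}

#' Write a model comparison as CSV
#'
#' Long layout: one row per model and sample with the day count, the WSAD,
#' and R1 (rounded to 3 decimals, as conventionally reported).
#'
#' @param x a \code{comparison_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$r1 <- round(df$r1, 3)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

exceedance_levels <- c("typical_both", "unusual_both",
                       "unusual_uncond_only", "unusual_cond_only")

#' Classify days by exceedance under two quantile thresholds
#'
#' Compares each day's count with the constant unconditional quantile and
#' with the day's conditional quantile.  A count exceeds a threshold only
#' if it lies strictly above it (a count equal to its quantile contributes
#' zero check loss, so it is "typical").  The four categories partition the
#' days: the interesting discordant ones are days unusual only under the
#' unconditional threshold (high counts that the season fully explains)
#' and days unusual only under the conditional threshold (counts
#' unremarkable in absolute terms but high for their season — e.g. summer
#' days that an annual threshold would never flag).
#'
#' @param y daily counts.
#' @param q_uncond the unconditional quantile (scalar, or one value per
#'   day).
#' @param q_cond per-day conditional quantiles, same length as \code{y}.
#' @return Factor of length \code{length(y)} with levels
#'   \code{typical_both}, \code{unusual_both}, \code{unusual_uncond_only},
#'   \code{unusual_cond_only}.
#' @examples
#' flag_exceedance(25, 20.2, 30)  # unusual under the annual threshold only
#' @export
flag_exceedance <- function(y, q_uncond, q_cond) {
  if (length(q_uncond) == 1L) q_uncond <- rep(q_uncond, length(y))
  if (length(q_cond) == 1L) q_cond <- rep(q_cond, length(y))
  if (length(y) != length(q_uncond) || length(y) != length(q_cond)) {
    stop("`y`, `q_uncond` and `q_cond` must have matching lengths",
         call. = FALSE)
  }
  above_u <- y > q_uncond
  above_c <- y > q_cond
  out <- ifelse(above_u & above_c, "unusual_both",
         ifelse(above_u & !above_c, "unusual_uncond_only",
         ifelse(!above_u & above_c, "unusual_cond_only", "typical_both")))
  factor(out, levels = exceedance_levels)
}

#' Per-day exceedance table for a fitted comparison
#'
#' Re-classifies every scored day (in- and out-sample) of one conditional
#' model against the unconditional model's constant threshold.
#'
#' @param comparison a \code{comparison_table} from
#'   \code{\link{evaluate_models}}.
#' @param model name of the conditional model to use (default
#'   \code{"M3_seasonal_lags"}).
#' @return data.frame: date, sample, deaths, q_uncond, q_cond, flag.
#' @export
exceedance_table <- function(comparison, model = "M3_seasonal_lags") {
  preds <- attr(comparison, "predictions")
  if (is.null(preds[[model]])) {
    stop("model not present in comparison: ", model, call. = FALSE)
  }
  uncond <- attr(comparison, "fits")[["M1_unconditional"]]$coefficients[[1L]]
  parts <- preds[[model]]
  out <- rbind(cbind(parts$in_sample, sample = "in"),
               cbind(parts$out_sample, sample = "out"))
  data.frame(date = out$date,
             sample = out$sample,
             deaths = out$deaths,
             q_uncond = uncond,
             q_cond = out$predicted,
             flag = flag_exceedance(out$deaths, uncond, out$predicted))
}
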