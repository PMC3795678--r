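#' Select the best single lag for one covariate
#'
#' Fits one conditional-quantile model per candidate lag — intercept,
#' optionally the seasonal/temporal base terms, and the single lagged
#' covariate — and picks the lag whose fit attains the smallest weighted
#' sum of absolute deviations.  All candidate fits use the identical set of
#' days: rows are restricted to the complete cases common to every
#' candidate lag, so the criterion values are comparable.  Ties break
#' toward the smallest lag (parsimony, and earlier availability when
#' forecasting).
#'
#' @param series a \code{daily_series}.
#' @param covariate name of the covariate column to lag.
#' @param tau quantile level (default 0.9).
#' @param candidate_lags integer vector of lags to try, each >= 1; default
#'   1:7.
#' @param base_terms if TRUE (default) the screening models include the
#'   cosinor and day-of-week terms, so a lag is judged on signal beyond
#'   seasonality.
#' @param origin cosinor time origin; defaults to the series' first date.
#' @param dow_reference reference weekday for the indicators.
#' @return An object of class \code{lag_selection}: \code{covariate},
#'   \code{wsad_by_lag} (named), \code{selected_lag}, \code{n_used}.
#' @export
select_lag <- function(series, covariate, tau = 0.9, candidate_lags = 1:7,
                       base_terms = TRUE, origin = NULL,
                       dow_reference = "sun") {
  series <- as_daily_series(series)
  check_tau(tau)
  if (!covariate %in% names(series)) {
    stop("covariate not present in series: ", covariate, call. = FALSE)
  }
  candidate_lags <- sort(unique(as.integer(candidate_lags)))
  if (length(candidate_lags) == 0L || any(candidate_lags < 1L)) {
    stop("`candidate_lags` must be a non-empty set of lags >= 1",
         call. = FALSE)
  }
  if (is.null(origin)) origin <- series$date[1L]

  base <- data.frame(intercept = rep(1, nrow(series)))
  if (base_terms) {
    base <- cbind(base, make_cosinor(series$date, origin),
                  make_dow_dummies(series$date, dow_reference))
  }
  lagged <- lapply(candidate_lags,
                   function(k) make_lag(series[[covariate]], k))
  names(lagged) <- paste0(covariate, "_lag", candidate_lags)

  keep <- !is.na(series$deaths)
  for (v in lagged) keep <- keep & !is.na(v)
  if (sum(keep) == 0L) {
    stop("covariate ", covariate,
         " has no complete rows after lagging", call. = FALSE)
  }
  y <- as.numeric(series$deaths[keep])
  Xbase <- as.matrix(base)[keep, , drop = FALSE]

  wsad <- vapply(seq_along(candidate_lags), function(i) {
    X <- cbind(Xbase, lagged[[i]][keep])
    colnames(X) <- c(colnames(Xbase), names(lagged)[i])
    rq_exchange(X, y, tau)$wsad
  }, numeric(1))
  names(wsad) <- as.character(candidate_lags)

  structure(list(covariate = covariate,
                 wsad_by_lag = wsad,
                 selected_lag = candidate_lags[which.min(wsad)],
                 n_used = sum(keep),
                 tau = tau,
                 base_terms = base_terms),
            class = "lag_selection")
}

#' @export
print.lag_selection <- function(x, ...) {
  cat(sprintf("Lag selection for %s (tau = %g, %d days): lag %d\n",
              x$covariate, x$tau, x$n_used, x$selected_lag))
  print(round(x$wsad_by_lag, 2))
  invisible(x)
}

#' Select lags for a list of covariates
#'
#' Applies \code{\link{select_lag}} independently to each covariate; the
#' result order matches the input order and feeds straight into the
#' seasonal-plus-lags model via \code{\link{lag_map}}.
#'
#' @inheritParams select_lag
#' @param covariates non-empty character vector of covariate names.
#' @return A list of \code{lag_selection} objects, class
#'   \code{lag_selection_list}.
#' @export
select_all_lags <- function(series, covariates = nmmaps_covariates,
                            tau = 0.9, candidate_lags = 1:7,
                            base_terms = TRUE, origin = NULL,
                            dow_reference = "sun") {
  if (length(covariates) == 0L) {
    stop("`covariates` must be non-empty", call. = FALSE)
  }
  out <- lapply(covariates, function(cv) {
    tryCatch(select_lag(series, cv, tau = tau,
                        candidate_lags = candidate_lags,
                        base_terms = base_terms, origin = origin,
                        dow_reference = dow_reference),
             error = function(e) {
               stop("lag selection failed for covariate ", cv, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  names(out) <- covariates
  structure(out, class = "lag_selection_list")
}

#' @export
print.lag_selection_list <- function(x, ...) {
  for (el in x) {
    cat(sprintf("  %-6s -> lag %d (WSAD %.2f)\n", el$covariate,
                el$selected_lag, min(el$wsad_by_lag)))
  }
  invisible(x)
}

#' Extract the covariate -> lag map from a selection result
#'
#' @param x a \code{lag_selection_list} (or a single \code{lag_selection}).
#' @return Named integer vector suitable for
#'   \code{model_spec("M3_seasonal_lags", lag_map = ...)}.
#' @export
lag_map <- function(x) {
  if (inherits(x, "lag_selection")) x <- list(x)
  vapply(x, function(el) as.integer(el$selected_lag), integer(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(x, function(el) el$covariate, character(1)))
}

#' Per-covariate WSAD-by-lag table
#'
#' @param x a \code{lag_selection_list}.
#' @return data.frame with one row per covariate x candidate lag.
#' @export
wsad_by_lag_table <- function(x) {
  do.call(rbind, lapply(x, function(el) {
    data.frame(covariate = el$covariate,
               lag = as.integer(names(el$wsad_by_lag)),
               wsad = unname(el$wsad_by_lag),
               selected = as.integer(names(el$wsad_by_lag)) ==
                 el$selected_lag,
               row.names = NULL)
  }))
}
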