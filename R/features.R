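#' @importFrom stats filter
NULL

# weekday index 0..6 (Sunday = 0), locale-independent: 1970-01-01 was a
# Thursday, i.e. day number 4
weekday_index <- function(dates) {
  (as.integer(as.Date(dates)) + 4L) %% 7L
}

weekday_names <- c("sun", "mon", "tue", "wed", "thu", "fri", "sat")

#' Cosinor (harmonic) seasonal terms
#'
#' Paired sine/cosine columns for a yearly (365.25 d) and a half-yearly
#' (182.625 d) cycle — the linear-in-parameters form of a cosinor, which
#' lets an ordinary linear fit estimate the amplitude and phase of seasonal
#' variation.  Time is measured in whole days elapsed since \code{origin},
#' so designs built for different subsamples of one study share a single
#' phase convention when given the same origin.
#'
#' @param dates vector of \code{Date}s (non-empty).
#' @param origin the \code{Date} at which t = 0.
#' @return A data.frame with columns \code{cos_year}, \code{sin_year},
#'   \code{cos_halfyear}, \code{sin_halfyear}.
#' @examples
#' make_cosinor(as.Date("1987-01-01"), origin = as.Date("1987-01-01"))
#' @export
make_cosinor <- function(dates, origin) {
  dates <- as.Date(dates)
  origin <- as.Date(origin)
  if (length(dates) == 0L) stop("`dates` must be non-empty", call. = FALSE)
  if (length(origin) != 1L || is.na(origin)) {
    stop("`origin` must be a single date", call. = FALSE)
  }
  t <- as.numeric(dates - origin)
  wy <- 2 * pi * t / 365.25
  wh <- 2 * pi * t / 182.625
  data.frame(cos_year = cos(wy), sin_year = sin(wy),
             cos_halfyear = cos(wh), sin_halfyear = sin(wh))
}

#' Day-of-week indicator columns
#'
#' One 0/1 column per non-reference weekday; rows falling on the reference
#' weekday are all-zero.  The weekday is computed arithmetically from the
#' date, independent of locale.
#'
#' @param dates vector of \code{Date}s.
#' @param reference the weekday absorbed into the intercept; one of
#'   \code{"sun"}, ..., \code{"sat"} (default \code{"sun"}).
#' @return A data.frame of six 0/1 columns named \code{dow_mon}, ...,
#'   ordered Sunday through Saturday with the reference omitted.
#' @export
make_dow_dummies <- function(dates, reference = "sun") {
  dates <- as.Date(dates)
  reference <- match.arg(tolower(reference), weekday_names)
  wd <- weekday_index(dates)
  keep <- setdiff(weekday_names, reference)
  out <- lapply(match(keep, weekday_names) - 1L,
                function(k) as.numeric(wd == k))
  names(out) <- paste0("dow_", keep)
  as.data.frame(out)
}

#' Lag a daily series by k calendar days
#'
#' The value at day t becomes the input value at day t - k; the first k
#' days, having no antecedent in the series, become missing, and missing
#' inputs propagate to their lagged position.
#'
#' @param series numeric vector indexed by consecutive calendar days.
#' @param k non-negative integer lag, strictly less than the series length.
#' @return Numeric vector of the same length.
#' @examples
#' make_lag(c(10, 20, 30), 1)  # NA 10 20
#' @export
make_lag <- function(series, k) {
  n <- length(series)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k)) {
    stop("`k` must be a single integer", call. = FALSE)
  }
  if (k < 0 || k >= n) {
    stop("`k` must satisfy 0 <= k <= length(series) - 1 (got k = ", k,
         ", length = ", n, ")", call. = FALSE)
  }
  if (k == 0) return(series)
  c(rep(NA_real_, k), series[seq_len(n - k)])
}

#' Trailing moving average of a daily series
#'
#' The value at day t is the mean of days t - window + 1 through t, i.e. a
#' trailing window that includes the current day and never looks into the
#' future — the alignment a forecast can actually use.  The result is
#' missing whenever the window extends before the series start or covers
#' any missing value.
#'
#' @param series numeric vector indexed by consecutive calendar days.
#' @param window integer window length, at least 2 (default 7).
#' @return Numeric vector of the same length.
#' @examples
#' make_moving_average(1:7, 7)  # NA ... NA 4
#' @export
make_moving_average <- function(series, window = 7) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window != round(window) || window < 2) {
    stop("`window` must be a single integer >= 2", call. = FALSE)
  }
  out <- stats::filter(as.numeric(series), rep(1 / window, window),
                       sides = 1)
  as.numeric(out)
}

model_names <- c("M1_unconditional", "M2_seasonal", "M3_seasonal_lags",
                 "M4_seasonal_ma")

#' Specify one of the four conditional-quantile model structures
#'
#' \describe{
#'   \item{M1_unconditional}{intercept only: a single constant quantile.}
#'   \item{M2_seasonal}{intercept + yearly and half-yearly cosinor terms +
#'     day-of-week indicators.}
#'   \item{M3_seasonal_lags}{M2 plus one lagged column per weather /
#'     air-quality covariate, lags given by \code{lag_map}.}
#'   \item{M4_seasonal_ma}{M2 plus one trailing moving-average column per
#'     covariate.}
#' }
#'
#' @param name one of the four model names (partial matching allowed).
#' @param lag_map named integer vector, covariate name -> lag in days
#'   (each in 1..7); required for and only allowed with M3.
#' @param ma_window trailing-window length in days for M4 (default 7).
#' @return An object of class \code{model_spec}.
#' @examples
#' model_spec("M3_seasonal_lags", lag_map = c(tmean = 3, o3 = 1))
#' @export
model_spec <- function(name, lag_map = NULL, ma_window = 7) {
  name <- match.arg(name, model_names)
  if (name == "M3_seasonal_lags") {
    if (is.null(lag_map) || length(lag_map) == 0L) {
      stop("M3_seasonal_lags requires a non-empty `lag_map`", call. = FALSE)
    }
    if (is.null(names(lag_map)) || any(!nzchar(names(lag_map)))) {
      stop("`lag_map` must be a named vector (covariate -> lag)",
           call. = FALSE)
    }
    lag_map <- vapply(lag_map, as.integer, integer(1))
    if (any(lag_map < 1L | lag_map > 7L)) {
      stop("every lag in `lag_map` must lie in 1..7", call. = FALSE)
    }
  } else if (!is.null(lag_map)) {
    stop("`lag_map` is only meaningful for M3_seasonal_lags", call. = FALSE)
  }
  if (name == "M4_seasonal_ma") {
    if (!is.numeric(ma_window) || length(ma_window) != 1L ||
        ma_window != round(ma_window) || ma_window < 2) {
      stop("`ma_window` must be a single integer >= 2", call. = FALSE)
    }
    ma_window <- as.integer(ma_window)
  } else {
    ma_window <- NA_integer_
  }
  structure(list(name = name, lag_map = lag_map, ma_window = ma_window),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", x$name, "\n")
  if (!is.null(x$lag_map)) {
    cat("  lags:", paste(names(x$lag_map), x$lag_map, sep = "=",
                         collapse = ", "), "\n")
  }
  if (!is.na(x$ma_window)) cat("  moving-average window:", x$ma_window, "\n")
  invisible(x)
}

#' Assemble the complete-case design matrix for a model
#'
#' Builds the predictor columns the model structure calls for, aligns them
#' with the daily death counts, and drops every day with any missing cell
#' in the response or the predictors (complete-case filtering; lagged and
#' moving-average columns make the first days of the series incomplete by
#' construction).  No value is fabricated: every retained cell is either a
#' source cell or a deterministic function of source cells.
#'
#' @param series a \code{daily_series} data.frame (see
#'   \code{\link{daily_series}}).
#' @param spec a \code{\link{model_spec}}.
#' @param origin the date at which cosinor time t = 0; defaults to the
#'   first date of \code{series}.  Pass the first date of the full dataset
#'   when assembling designs for subsamples, so all samples share one
#'   seasonal phase.
#' @param dow_reference reference weekday for the indicators (default
#'   \code{"sun"}).
#' @return An object of class \code{design_matrix}: a list with
#'   \code{dates}, \code{X} (named numeric matrix, intercept first),
#'   \code{y} (response aligned to \code{dates}), \code{dropped_days},
#'   and \code{spec}.
#' @export
assemble_design <- function(series, spec, origin = NULL,
                            dow_reference = "sun") {
  series <- as_daily_series(series)
  if (!inherits(spec, "model_spec")) {
    stop("`spec` must be a model_spec", call. = FALSE)
  }
  if (is.null(origin)) origin <- series$date[1L]
  n <- nrow(series)
  cols <- data.frame(intercept = rep(1, n))
  if (spec$name != "M1_unconditional") {
    cols <- cbind(cols, make_cosinor(series$date, origin),
                  make_dow_dummies(series$date, dow_reference))
  }
  if (spec$name == "M3_seasonal_lags") {
    missing_cov <- setdiff(names(spec$lag_map), names(series))
    if (length(missing_cov) > 0L) {
      stop("lag_map covariate(s) absent from series: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    for (cv in names(spec$lag_map)) {
      cols[[paste0(cv, "_lag", spec$lag_map[[cv]])]] <-
        make_lag(series[[cv]], spec$lag_map[[cv]])
    }
  }
  if (spec$name == "M4_seasonal_ma") {
    covs <- intersect(nmmaps_covariates, names(series))
    if (length(covs) == 0L) {
      stop("series has none of the expected covariate columns", call. = FALSE)
    }
    for (cv in covs) {
      cols[[paste0(cv, "_ma", spec$ma_window)]] <-
        make_moving_average(series[[cv]], spec$ma_window)
    }
  }
  X <- as.matrix(cols)
  y <- as.numeric(series$deaths)
  keep <- stats::complete.cases(X) & !is.na(y)
  structure(list(dates = series$date[keep],
                 X = X[keep, , drop = FALSE],
                 y = y[keep],
                 dropped_days = as.integer(n - sum(keep)),
                 spec = spec),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix for %s: %d days x %d columns (%d days dropped)\n",
              x$spec$name, length(x$y), ncol(x$X), x$dropped_days))
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
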