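#' Weather and air-quality covariates of the daily series
#'
#' Column names of the six daily exposure covariates: mean temperature,
#' dew point, ozone, sulphur dioxide, nitrogen dioxide, carbon monoxide.
#' @export
nmmaps_covariates <- c("tmean", "dptp", "o3", "so2", "no2", "co")

#' Construct and validate a daily mortality series
#'
#' The raw input of the whole pipeline: one row per calendar day, with the
#' daily respiratory death count and the six weather / air-quality
#' covariates.  Counts and covariates may be missing; dates may not.
#'
#' @param df data.frame with a \code{date} column (coercible to
#'   \code{Date}), a \code{deaths} column of non-negative integers (NA
#'   allowed), and any subset of the covariate columns listed in
#'   \code{\link{nmmaps_covariates}}.
#' @return The validated data.frame with class \code{daily_series}.
#' @export
daily_series <- function(df) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame", call. = FALSE)
  if (!"date" %in% names(df)) stop("missing column: date", call. = FALSE)
  if (!"deaths" %in% names(df)) stop("missing column: deaths", call. = FALSE)
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("column date contains unparseable values",
                           call. = FALSE)
  if (anyDuplicated(df$date)) {
    dup <- df$date[duplicated(df$date)][1L]
    stop("duplicated date: ", format(dup), call. = FALSE)
  }
  if (is.unsorted(df$date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  d <- df$deaths[!is.na(df$deaths)]
  if (length(d) > 0L) {
    if (!is.numeric(d) || any(d < 0) || any(d != round(d))) {
      bad <- which(!is.na(df$deaths) &
                     (df$deaths < 0 | df$deaths != round(df$deaths)))[1L]
      stop("column deaths must hold non-negative integers; offending row ",
           bad, " (date ", format(df$date[bad]), ")", call. = FALSE)
    }
  }
  for (cv in intersect(nmmaps_covariates, names(df))) {
    if (!is.numeric(df[[cv]]) && !all(is.na(df[[cv]]))) {
      stop("covariate column ", cv, " must be numeric", call. = FALSE)
    }
    df[[cv]] <- as.numeric(df[[cv]])
  }
  class(df) <- unique(c("daily_series", class(df)))
  df
}

as_daily_series <- function(x) {
  if (inherits(x, "daily_series")) return(x)
  daily_series(x)
}

#' Write a daily series to CSV
#'
#' ISO-8601 dates, one row per day, empty cells for missing values — the
#' on-disk dialect the pipeline's reader expects.
#'
#' @param series a \code{daily_series}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_daily_series <- function(series, path) {
  series <- as_daily_series(series)
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
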