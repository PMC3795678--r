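#' Read and validate a daily series CSV
#'
#' Parses the pipeline's CSV dialect (columns \code{date}, \code{deaths},
#' and the weather / air-quality covariates; empty cell = missing),
#' enforces the series invariants, and materializes calendar gaps as
#' all-missing rows so that lag and moving-average alignment stays
#' calendar-true.
#'
#' @param path path to a CSV file.
#' @return A \code{\link{daily_series}}.
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!"date" %in% names(raw)) stop("missing column: date", call. = FALSE)
  if (!"deaths" %in% names(raw)) stop("missing column: deaths", call. = FALSE)
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(raw$date))
  if (length(bad) > 0L) {
    stop("column date, row ", bad[1L], ": cannot parse value '",
         raw$date[bad[1L]], "'", call. = FALSE)
  }
  if (anyNA(dates)) stop("column date contains empty cells", call. = FALSE)
  raw$date <- dates
  if (anyDuplicated(dates)) {
    stop("duplicated date: ", format(dates[duplicated(dates)][1L]),
         call. = FALSE)
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    i <- which(diff(as.integer(dates)) <= 0)[1L] + 1L
    stop("dates not strictly increasing at row ", i, " (",
         format(dates[i]), ")", call. = FALSE)
  }
  if (!is.numeric(raw$deaths) && !all(is.na(raw$deaths))) {
    bad <- which(!is.na(raw$deaths) &
                   is.na(suppressWarnings(as.numeric(raw$deaths))))[1L]
    stop("column deaths, row ", bad, ": non-numeric value '",
         raw$deaths[bad], "'", call. = FALSE)
  }
  raw$deaths <- suppressWarnings(as.numeric(raw$deaths))
  bad <- which(!is.na(raw$deaths) &
                 (raw$deaths < 0 | raw$deaths != round(raw$deaths)))
  if (length(bad) > 0L) {
    stop("column deaths, row ", bad[1L], " (date ",
         format(raw$date[bad[1L]]), "): value ", raw$deaths[bad[1L]],
         " is not a non-negative integer", call. = FALSE)
  }

  full_dates <- seq(min(dates), max(dates), by = "day")
  if (length(full_dates) > nrow(raw)) {
    gap_n <- length(full_dates) - nrow(raw)
    warning("calendar has ", gap_n, " missing day(s); inserting all-missing ",
            "rows to keep lags calendar-true", call. = FALSE)
    filled <- data.frame(date = full_dates)
    raw <- merge(filled, raw, by = "date", all.x = TRUE, sort = TRUE)
  }
  daily_series(raw)
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of \code{input} (a CSV path) or \code{synthetic} (a
#' \code{\link{synthetic_config}}) must be given.
#'
#' @param input path to a daily-series CSV, or NULL.
#' @param synthetic a \code{synthetic_config}, or NULL.
#' @param tau quantile level in (0, 1).
#' @param cutoff in-/out-sample split date; default NULL splits at the
#'   series midpoint.
#' @param candidate_lags lags screened per covariate (subset of 1..7 by
#'   default).
#' @param ma_window trailing moving-average window for the fourth model.
#' @param jitter NULL, or list(amount=, seed=) for response jittering.
#' @param dow_reference reference weekday.
#' @param covariates covariate columns to use.
#' @param output_dir directory for run artifacts.
#' @param seed integer seed for any stochastic stage.
#' @param log_level "info" or "quiet".
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(input = NULL, synthetic = NULL, tau = 0.9,
                       cutoff = NULL, candidate_lags = 1:7, ma_window = 7,
                       jitter = NULL, dow_reference = "sun",
                       covariates = nmmaps_covariates,
                       output_dir = tempfile("qrsurveil_run_"),
                       seed = 1L, log_level = c("info", "quiet")) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of `input` and `synthetic` must be given",
         call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    stop("`synthetic` must come from synthetic_config()", call. = FALSE)
  }
  check_tau(tau)
  candidate_lags <- sort(unique(as.integer(candidate_lags)))
  if (any(candidate_lags < 1L | candidate_lags > 7L)) {
    stop("`candidate_lags` must be a subset of 1..7", call. = FALSE)
  }
  structure(list(input = input, synthetic = synthetic, tau = tau,
                 cutoff = if (!is.null(cutoff)) as.Date(cutoff),
                 candidate_lags = candidate_lags,
                 ma_window = as.integer(ma_window), jitter = jitter,
                 dow_reference = dow_reference, covariates = covariates,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Run the full surveillance analysis pipeline
#'
#' Stages: obtain the series (read + validate, or simulate), split at the
#' cutoff, screen lags per covariate on the in-sample days, fit the four
#' model structures in-sample, score prediction and forecasting by WSAD
#' and R1, and classify every day's exceedance status under the
#' unconditional versus the conditional threshold.  All artifacts — series
#' CSV (when simulated), lag map JSON, WSAD-by-lag CSV, fit coefficients
#' JSON, comparison CSV, exceedance CSV, log, and a manifest with the
#' configuration and per-file MD5 checksums — are written under
#' \code{config$output_dir}.  Runs are deterministic given the
#' configuration and seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list: \code{series}, \code{lag_selection},
#'   \code{comparison}, \code{exceedance}, \code{artifacts} (file paths),
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("`config` must come from run_config()", call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    if (config$log_level == "info") message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      say("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  artifacts <- character(0)
  keep <- function(path) {
    artifacts[[basename(path)]] <<- path
    path
  }

  sim <- NULL
  series <- stage("input", {
    if (!is.null(config$input)) {
      validate_input(config$input)
    } else {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      sim <- simulate_daily_series(cfg)
      write_daily_series(sim$series, keep(file.path(config$output_dir,
                                                    "series.csv")))
      write_ground_truth(sim, keep(file.path(config$output_dir,
                                             "ground_truth.json")))
      sim$series
    }
  })
  say("series: ", nrow(series), " days, ",
      sum(is.na(series$deaths)), " missing counts")

  cutoff <- config$cutoff
  if (is.null(cutoff)) {
    cutoff <- series$date[ceiling(nrow(series) / 2)]
    say("cutoff defaulted to series midpoint: ", format(cutoff))
  }
  halves <- stage("split", split_sample(series, cutoff))
  origin <- series$date[1L]

  covs <- intersect(config$covariates, names(series))
  sel <- stage("select_lags", {
    select_all_lags(halves$in_sample, covariates = covs, tau = config$tau,
                    candidate_lags = config$candidate_lags,
                    origin = origin, dow_reference = config$dow_reference)
  })
  say("selected lags: ", paste(names(lag_map(sel)), lag_map(sel),
                               sep = "=", collapse = ", "))
  jsonlite::write_json(as.list(lag_map(sel)),
                       keep(file.path(config$output_dir, "lag_map.json")),
                       auto_unbox = TRUE)
  utils::write.csv(wsad_by_lag_table(sel),
                   keep(file.path(config$output_dir, "wsad_by_lag.csv")),
                   row.names = FALSE)

  specs <- list(model_spec("M1_unconditional"),
                model_spec("M2_seasonal"),
                model_spec("M3_seasonal_lags", lag_map = lag_map(sel)),
                model_spec("M4_seasonal_ma", ma_window = config$ma_window))
  comparison <- stage("evaluate", {
    evaluate_models(series, specs, tau = config$tau, cutoff = cutoff,
                    origin = origin, dow_reference = config$dow_reference,
                    jitter = config$jitter)
  })
  write_comparison_csv(comparison,
                       keep(file.path(config$output_dir, "comparison.csv")))
  fits <- attr(comparison, "fits")
  jsonlite::write_json(
    lapply(fits, function(f) list(tau = f$tau,
                                  coefficients = as.list(f$coefficients),
                                  n_used = f$n_used,
                                  train_wsad = f$train_wsad,
                                  jitter = f$jitter)),
    keep(file.path(config$output_dir, "fits.json")),
    auto_unbox = TRUE, digits = NA)

  exceed <- stage("exceedance", exceedance_table(comparison))
  utils::write.csv(exceed,
                   keep(file.path(config$output_dir, "exceedance.csv")),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("qrsurveil")),
    seed = config$seed,
    tau = config$tau,
    cutoff = format(cutoff),
    candidate_lags = config$candidate_lags,
    ma_window = config$ma_window,
    dow_reference = config$dow_reference,
    input = config$input,
    synthetic = !is.null(config$synthetic),
    config_hash = hash_object(strip_paths(config)),
    checksums = as.list(tools::md5sum(unlist(artifacts))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest,
                       keep(file.path(config$output_dir, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  say("run complete: ", length(artifacts), " artifacts in ",
      config$output_dir)

  invisible(list(series = series, lag_selection = sel,
                 comparison = comparison, exceedance = exceed,
                 artifacts = artifacts, manifest = manifest))
}

# configuration hash that ignores machine-local paths
strip_paths <- function(config) {
  config$output_dir <- NULL
  config
}

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration from a YAML or JSON file
#'
#' File keys mirror the arguments of \code{\link{run_config}}; a
#' \code{synthetic} block mirrors \code{\link{synthetic_config}}.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  if (!is.null(raw$candidate_lags)) {
    raw$candidate_lags <- as.integer(unlist(raw$candidate_lags))
  }
  do.call(run_config, raw)
}
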