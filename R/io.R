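# parse a timestamp column: numeric minutes pass through; ISO-8601 datetimes
# become minutes from the first sample's midnight (local clock)
parse_times <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!any(is.na(num))) return(num)
  tt <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC",
                   optional = TRUE)
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%d %H:%M")) {
    miss <- is.na(tt)
    if (!any(miss)) break
    tt[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  if (any(is.na(tt))) {
    bad <- which(is.na(tt))[1]
    stop("unparseable timestamp at line ", bad + 1L, ": '", x[bad], "'",
         call. = FALSE)
  }
  midnight <- as.POSIXct(format(tt[1], "%Y-%m-%d"), tz = "UTC")
  as.numeric(difftime(tt, midnight, units = "mins"))
}

#' Read a two-column time-series CSV
#'
#' Reads a glucose (mg/dl) or activity (counts/min) time series from a CSV
#' with a timestamp column (numeric minutes or ISO-8601) and a value column.
#' The series is validated: times must be strictly increasing without
#' duplicates, glucose must lie within the 20-600 mg/dl sensor range and
#' counts must be nonnegative. Grid gaps are reported via a message.
#'
#' @param path CSV file path.
#' @param kind `"glucose"` or `"activity"`.
#' @return Data frame with columns `time` (min) and `glucose` or `counts`.
#' @export
read_timeseries_csv <- function(path, kind = c("glucose", "activity")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a two-column CSV", call. = FALSE)
  time <- parse_times(df[[1]])
  value <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(value))) {
    bad <- which(is.na(value))[1]
    stop("unparseable value at line ", bad + 1L, call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1]
    stop("timestamps not strictly increasing at line ", bad + 2L, call. = FALSE)
  }
  if (kind == "glucose") {
    if (any(value <= 20 | value >= 600)) {
      bad <- which(value <= 20 | value >= 600)[1]
      stop("glucose value out of sensor range (20, 600) mg/dl at line ",
           bad + 1L, call. = FALSE)
    }
    out <- data.frame(time = time, glucose = value)
    step <- stats::median(diff(time))
    gaps <- sum(diff(time) > 1.5 * step)
    if (gaps > 0) message(gaps, " gap(s) detected in the glucose series")
  } else {
    if (any(value < 0)) stop("counts must be nonnegative", call. = FALSE)
    out <- data.frame(time = time, counts = value)
  }
  out
}

#' Write a two-column time-series CSV
#'
#' @param series data frame from [read_timeseries_csv()] (columns `time` and
#'   `glucose`/`counts`).
#' @param path output CSV file path.
#' @return The path, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario description from JSON or YAML
#'
#' The schema mirrors [scenario()]: `t_start`/`t_end` (minutes or `"HH:MM"`),
#' `meals` (list of `{time, cho_g, f?, tau_m?, label?}`), `boluses` (list of
#' `{time, dose_U, label?}`), `basal` (U/h scalar or list of
#' `{time, rate_Uh}`), and `activity` as either `{bouts: [{start, duration,
#' intensity}]}` or `{csv: "path"}` (resolved relative to the scenario
#' file).
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A `glucopa_scenario`.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML scenarios", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = FALSE)
  meals <- lapply(doc$meals, function(m)
    meal_event(m$time, m$cho_g,
               f = if (is.null(m$f)) 0.9 else m$f,
               tau_m = if (is.null(m$tau_m)) 40 else m$tau_m,
               label = m$label))
  boluses <- lapply(doc$boluses, function(b)
    insulin_bolus(b$time, b$dose_U, label = b$label))
  basal <- doc$basal
  if (is.list(basal))
    basal <- data.frame(
      time = vapply(basal, function(r) parse_clock(r$time), numeric(1)),
      rate_Uh = vapply(basal, function(r) as.numeric(r$rate_Uh), numeric(1)))
  if (is.null(basal)) basal <- 0.8
  activity <- NULL
  if (!is.null(doc$activity)) {
    if (!is.null(doc$activity$csv)) {
      csv <- doc$activity$csv
      if (!file.exists(csv)) csv <- file.path(dirname(path), csv)
      activity <- read_timeseries_csv(csv, "activity")
    } else if (!is.null(doc$activity$bouts)) {
      bouts <- do.call(rbind, lapply(doc$activity$bouts, function(b)
        data.frame(start = parse_clock(b$start), duration = b$duration,
                   intensity = b$intensity)))
      activity <- ac_trace_from_bouts(bouts)
    }
  }
  scenario(t_end = doc$t_end,
           t_start = if (is.null(doc$t_start)) 0 else doc$t_start,
           meals = meals, boluses = boluses, basal = basal,
           activity = activity)
}

#' Write a simulated trajectory as tidy CSV
#'
#' @param sim a `glucopa_sim`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  cols <- c("time", "G", "I", "Q1", "Q2", "X", "Y", "Z",
            "rGU", "rGP", "rdepl", "GP", "GU", "Ra", "AC")
  utils::write.csv(sim$trajectory[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a run-provenance sidecar
#'
#' Records everything needed to reproduce a run: package version, seed,
#' solver settings and the full parameter set.
#'
#' @param dir output directory.
#' @param seed integer seed used for the run (or `NULL`).
#' @param params a `glucopa_params` (or `NULL`).
#' @param extra named list of additional fields (e.g. the run config).
#' @return The file path, invisibly.
#' @export
write_provenance <- function(dir, seed = NULL, params = NULL, extra = list()) {
  info <- c(list(package = "glucopa",
                 version = as.character(utils::packageVersion("glucopa")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 seed = seed,
                 parameters = if (!is.null(params)) unclass(params)),
            extra)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
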