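#' Meal event
#'
#' A carbohydrate meal whose glucose appearance in plasma follows the
#' gamma-shaped kernel `Ra(t) = f * D * (t - t0) / tau_m^2 * exp(-(t - t0)/tau_m)`
#' for `t >= t0`. The absorbed fraction `f` and the time constant `tau_m`
#' (which equals the time from meal start to maximum appearance rate) are
#' carried per meal, so they can be fitted meal by meal.
#'
#' @param t0 meal start time, min from scenario start (or `"HH:MM"` clock time).
#' @param cho_g carbohydrate content, g (stored internally in mg).
#' @param f absorbed fraction, in (0, 1].
#' @param tau_m appearance time constant, min.
#' @param label optional label used by replay selectors.
#' @return A `glucopa_meal` object.
#' @export
meal_event <- function(t0, cho_g, f = 0.9, tau_m = 40, label = NULL) {
  t0 <- parse_clock(t0)
  if (!is.finite(cho_g) || cho_g <= 0) stop("'cho_g' must be positive", call. = FALSE)
  if (!is.finite(f) || f <= 0 || f > 1) stop("'f' must be in (0, 1]", call. = FALSE)
  if (!is.finite(tau_m) || tau_m <= 0) stop("'tau_m' must be positive", call. = FALSE)
  structure(list(t0 = t0, D = cho_g * 1000, f = f, tau_m = tau_m,
                 label = label), class = "glucopa_meal")
}

#' Insulin bolus event
#'
#' A rapid-acting insulin bolus, delivered as an instantaneous addition of
#' the full dose to the first subcutaneous compartment at `t0` (a Dirac input
#' to the injection cascade; the integrator restarts at the event).
#'
#' @param t0 injection time, min from scenario start (or `"HH:MM"`).
#' @param dose_U dose in insulin units U (1 U = 1e6 uU).
#' @param label optional label used by replay selectors.
#' @return A `glucopa_bolus` object.
#' @export
insulin_bolus <- function(t0, dose_U, label = NULL) {
  t0 <- parse_clock(t0)
  if (!is.finite(dose_U) || dose_U < 0) stop("'dose_U' must be nonnegative", call. = FALSE)
  structure(list(t0 = t0, dose_U = dose_U, label = label),
            class = "glucopa_bolus")
}

#' Activity trace from structured exercise bouts
#'
#' Builds a minute-resolution accelerometer-count trace from a list of bouts,
#' each held at the constant count corresponding to its %VO2max intensity via
#' [ac_from_vo2max()], with zero counts elsewhere.
#'
#' @param bouts data frame with columns `start` (min), `duration` (min) and
#'   `intensity` (%VO2max, at least the resting intercept 1.7228), or a list
#'   of such triples.
#' @param t_end optional end of the trace grid, min.
#' @return Data frame with columns `time` (min, minute grid) and `counts`
#'   (counts/min), piecewise constant over `[time, time + 1)`.
#' @export
ac_trace_from_bouts <- function(bouts, t_end = NULL) {
  if (is.list(bouts) && !is.data.frame(bouts))
    bouts <- do.call(rbind, lapply(bouts, function(b) as.data.frame(b)))
  if (is.null(bouts) || nrow(bouts) == 0) {
    t_end <- if (is.null(t_end)) 0 else t_end
    return(data.frame(time = seq(0, max(0, t_end - 1)), counts = 0))
  }
  stopifnot(all(c("start", "duration", "intensity") %in% names(bouts)))
  bouts <- bouts[order(bouts$start), , drop = FALSE]
  ends <- bouts$start + bouts$duration
  if (any(bouts$duration <= 0)) stop("bout durations must be positive", call. = FALSE)
  if (nrow(bouts) > 1 && any(bouts$start[-1] < ends[-nrow(bouts)]))
    stop("activity bouts overlap", call. = FALSE)
  if (is.null(t_end)) t_end <- max(ends)
  tt <- seq(0, ceiling(t_end) - 1)
  counts <- numeric(length(tt))
  for (i in seq_len(nrow(bouts))) {
    sel <- tt >= bouts$start[i] & tt < ends[i]
    counts[sel] <- ac_from_vo2max(bouts$intensity[i])
  }
  data.frame(time = tt, counts = counts)
}

#' Validate an accelerometer trace
#'
#' @param trace data frame with columns `time` (min, strictly increasing) and
#'   `counts` (counts/min, nonnegative). Counts are treated as piecewise
#'   constant over `[time[i], time[i+1])`; gaps are treated as zero counts by
#'   the consumer.
#' @return The validated trace (invisibly the same data frame).
#' @export
activity_trace <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time", "counts") %in% names(trace)))
  if (any(!is.finite(trace$time)) || any(diff(trace$time) <= 0))
    stop("trace times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(trace$counts)) || any(trace$counts < 0))
    stop("trace counts must be finite and nonnegative", call. = FALSE)
  trace[c("time", "counts")]
}

#' Simulation scenario
#'
#' Bundles the time horizon with all exogenous inputs: meals, insulin boluses,
#' the basal infusion schedule and the activity trace.
#'
#' @param t_end end of the horizon, min (or `"HH:MM"`).
#' @param t_start start of the horizon, min (default 0 = midnight when clock
#'   times are used).
#' @param meals list of [meal_event()] objects.
#' @param boluses list of [insulin_bolus()] objects.
#' @param basal basal insulin schedule: a single rate in U/h, or a data frame
#'   with columns `time` (min) and `rate_Uh` giving step changes (the rate in
#'   row i applies from `time[i]` until the next change).
#' @param activity optional activity trace (see [activity_trace()]), or
#'   `NULL` for a fully sedentary scenario.
#' @return A `glucopa_scenario` object.
#' @export
scenario <- function(t_end, t_start = 0, meals = list(), boluses = list(),
                     basal = 0.8, activity = NULL) {
  t_start <- parse_clock(t_start); t_end <- parse_clock(t_end)
  if (!is.finite(t_end) || t_end <= t_start)
    stop("'t_end' must exceed 't_start'", call. = FALSE)
  if (inherits(meals, "glucopa_meal")) meals <- list(meals)
  if (inherits(boluses, "glucopa_bolus")) boluses <- list(boluses)
  stopifnot(all(vapply(meals, inherits, logical(1), "glucopa_meal")),
            all(vapply(boluses, inherits, logical(1), "glucopa_bolus")))
  if (is.numeric(basal) && length(basal) == 1L)
    basal <- data.frame(time = t_start, rate_Uh = basal)
  stopifnot(is.data.frame(basal), all(c("time", "rate_Uh") %in% names(basal)))
  if (any(diff(basal$time) <= 0))
    stop("basal schedule times must be strictly increasing ",
         "(at most one rate active at a time)", call. = FALSE)
  if (any(basal$rate_Uh < 0)) stop("basal rates must be nonnegative", call. = FALSE)
  # a meal may start before the horizon (its absorption tail is still an
  # input); boluses are state jumps and must lie inside the horizon
  for (ev in meals) {
    if (ev$t0 > t_end)
      stop("meal at t=", ev$t0, " lies beyond the horizon end ", t_end,
           call. = FALSE)
  }
  for (ev in boluses) {
    if (ev$t0 < t_start || ev$t0 > t_end)
      stop("bolus at t=", ev$t0, " lies outside the horizon [",
           t_start, ", ", t_end, "]", call. = FALSE)
  }
  if (!is.null(activity)) activity <- activity_trace(activity)
  ord <- order(vapply(meals, `[[`, numeric(1), "t0"))
  meals <- meals[ord]
  ord <- order(vapply(boluses, `[[`, numeric(1), "t0"))
  boluses <- boluses[ord]
  structure(list(t_start = t_start, t_end = t_end, meals = meals,
                 boluses = boluses, basal = basal, activity = activity),
            class = "glucopa_scenario")
}

#' @export
print.glucopa_scenario <- function(x, ...) {
  cat(sprintf("<glucopa_scenario> horizon [%g, %g] min\n", x$t_start, x$t_end))
  cat(sprintf("  meals: %d  boluses: %d  basal steps: %d  activity rows: %d\n",
              length(x$meals), length(x$boluses), nrow(x$basal),
              if (is.null(x$activity)) 0L else nrow(x$activity)))
  invisible(x)
}

#' Glucose appearance rate of a single meal
#'
#' @param t time(s), min.
#' @param meal a [meal_event()] object.
#' @return Appearance rate `Ra` in mg/min (zero before the meal).
#' @export
meal_ra <- function(t, meal) {
  dt <- t - meal$t0
  ifelse(dt >= 0,
         meal$f * meal$D * dt / meal$tau_m^2 * exp(-dt / meal$tau_m),
         0)
}

#' Total glucose appearance from all meals
#'
#' Superposition of the per-meal appearance kernels, each meal keeping its
#' own absorbed fraction and time constant.
#'
#' @param t time(s), min.
#' @param meals list of [meal_event()] objects.
#' @return Total `Ra` in mg/min.
#' @export
total_ra <- function(t, meals) {
  if (length(meals) == 0L) return(numeric(length(t)))
  Reduce(`+`, lapply(meals, function(m) meal_ra(t, m)))
}

# "HH:MM" -> minutes from midnight; numerics pass through
parse_clock <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2L) stop("clock times must be 'HH:MM'", call. = FALSE)
      as.numeric(p[1]) * 60 + as.numeric(p[2])
    }, numeric(1))
  } else {
    as.numeric(x)
  }
}

# step-function lookup of the basal rate (uU/min) at time t
basal_rate_at <- function(sc, t) {
  idx <- findInterval(t, sc$basal$time)
  rate <- ifelse(idx == 0, sc$basal$rate_Uh[1], sc$basal$rate_Uh[pmax(idx, 1)])
  uU_per_min_from_U_per_h(rate)
}

# piecewise-constant AC lookup; gaps and times outside the trace are 0
ac_at <- function(trace, t) {
  if (is.null(trace) || nrow(trace) == 0L) return(numeric(length(t)) * 0)
  idx <- findInterval(t, trace$time)
  out <- numeric(length(t))
  inside <- idx >= 1
  out[inside] <- trace$counts[idx[inside]]
  # beyond the last sample + 1 min the trace has ended
  tmax <- trace$time[nrow(trace)] + 1
  out[t >= tmax] <- 0
  out
}

#' Standard three-meal day with one activity session
#'
#' Builds the package's standard full-day scenario for a 50 kg virtual
#' subject: meals at 07:00, 13:00 and 19:00 with 40, 60 and 50 g
#' carbohydrate, meal boluses at a 10 g/U carb ratio (4, 6 and 5 U), basal
#' insulin at 0.8 U/h, and optionally one constant-intensity activity bout in
#' the morning (starting 09:30) or afternoon (starting 15:30). The horizon is
#' 30 h so the night following the day (24:00-06:00) is simulated.
#'
#' @param pa_time `"none"`, `"morning"` or `"afternoon"`.
#' @param intensity exercise intensity, %VO2max (meaningful range ~(5, 95)).
#' @param duration bout duration, min.
#' @return A `glucopa_scenario` object.
#' @export
build_standard_day <- function(pa_time = c("none", "morning", "afternoon"),
                               intensity = 60, duration = 60) {
  pa_time <- match.arg(pa_time)
  meals <- list(meal_event("07:00", 40, label = "breakfast"),
                meal_event("13:00", 60, label = "lunch"),
                meal_event("19:00", 50, label = "dinner"))
  boluses <- list(insulin_bolus("07:00", 4, label = "breakfast"),
                  insulin_bolus("13:00", 6, label = "lunch"),
                  insulin_bolus("19:00", 5, label = "dinner"))
  activity <- NULL
  if (pa_time != "none") {
    if (!is.finite(duration) || duration <= 0)
      stop("'duration' must be positive", call. = FALSE)
    start <- if (pa_time == "morning") parse_clock("09:30") else parse_clock("15:30")
    meal_times <- vapply(meals, `[[`, numeric(1), "t0")
    if (any(meal_times > start & meal_times < start + duration))
      stop("activity bout overlaps a meal; shorten the bout or move it",
           call. = FALSE)
    activity <- ac_trace_from_bouts(
      data.frame(start = start, duration = duration, intensity = intensity),
      t_end = start + duration)
  }
  scenario(t_end = 1800, meals = meals, boluses = boluses,
           basal = 0.8, activity = activity)
}
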