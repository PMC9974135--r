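#' Recorded day of free-living data
#'
#' Container for the three data streams used for personalization and replay:
#' CGM glucose, accelerometer counts, and the self-reported logbook (meals
#' and insulin), plus body weight.
#'
#' @param cgm data frame with columns `time` (min, ~5-min grid, gaps allowed)
#'   and `glucose` (mg/dl, must lie in the open interval (20, 600)).
#' @param activity data frame with columns `time` (min, minute grid) and
#'   `counts` (counts/min), or `NULL`.
#' @param meals data frame with columns `time` (min) and `cho_g` (g), or
#'   `NULL`/empty if no meals were logged.
#' @param boluses data frame with columns `time` (min) and `dose_U`, or
#'   `NULL`.
#' @param basal basal insulin schedule: single rate in U/h or a data frame
#'   `time`/`rate_Uh`.
#' @param BW body weight, kg.
#' @return A `glucopa_day` object.
#' @export
recorded_day <- function(cgm, activity = NULL, meals = NULL, boluses = NULL,
                         basal = 0.8, BW = 50) {
  stopifnot(is.data.frame(cgm), all(c("time", "glucose") %in% names(cgm)))
  if (any(!is.finite(cgm$glucose)) ||
      any(cgm$glucose <= 20) || any(cgm$glucose >= 600))
    stop("CGM glucose values must lie in (20, 600) mg/dl", call. = FALSE)
  if (any(diff(cgm$time) <= 0))
    stop("CGM times must be strictly increasing", call. = FALSE)
  tmin <- cgm$time[1]; tmax <- cgm$time[length(cgm$time)]
  if (!is.null(activity)) {
    activity <- activity_trace(activity)
    tmin <- min(tmin, activity$time[1])
    tmax <- max(tmax, activity$time[nrow(activity)])
  }
  if (!is.null(meals) && nrow(meals) > 0) {
    stopifnot(all(c("time", "cho_g") %in% names(meals)))
  } else meals <- data.frame(time = numeric(0), cho_g = numeric(0))
  if (!is.null(boluses) && nrow(boluses) > 0) {
    stopifnot(all(c("time", "dose_U") %in% names(boluses)))
  } else boluses <- data.frame(time = numeric(0), dose_U = numeric(0))
  if (tmax - tmin > 1441)
    stop("a recorded day must span at most 24 h", call. = FALSE)
  if (is.numeric(basal) && length(basal) == 1L)
    basal <- data.frame(time = min(0, tmin), rate_Uh = basal)
  structure(list(cgm = cgm[c("time", "glucose")], activity = activity,
                 meals = meals, boluses = boluses, basal = basal, BW = BW),
            class = "glucopa_day")
}

#' @export
print.glucopa_day <- function(x, ...) {
  cat(sprintf("<glucopa_day> %d CGM points, %d meals, %d boluses, BW %g kg\n",
              nrow(x$cgm), nrow(x$meals), nrow(x$boluses), x$BW))
  invisible(x)
}

#' Build a simulation scenario from a recorded day
#'
#' Turns the logbook events and the accelerometer trace of a recorded day
#' into a [scenario()]. Per-meal absorption parameters come from
#' `meal_params` (a data frame with columns `f` and `tau_m`, one row per
#' logged meal) or default to `f = 0.9`, `tau_m = 40` min.
#'
#' @param day a `glucopa_day`.
#' @param meal_params optional data frame of per-meal `f` and `tau_m`.
#' @param t_end optional horizon end, min (default: last CGM time).
#' @return A `glucopa_scenario`.
#' @export
day_to_scenario <- function(day, meal_params = NULL, t_end = NULL) {
  stopifnot(inherits(day, "glucopa_day"))
  nm <- nrow(day$meals)
  if (is.null(meal_params)) {
    meal_params <- data.frame(f = rep(0.9, nm), tau_m = rep(40, nm))
  }
  stopifnot(nrow(meal_params) == nm)
  meals <- lapply(seq_len(nm), function(i)
    meal_event(day$meals$time[i], day$meals$cho_g[i],
               f = meal_params$f[i], tau_m = meal_params$tau_m[i],
               label = paste0("meal", i)))
  boluses <- lapply(seq_len(nrow(day$boluses)), function(i)
    insulin_bolus(day$boluses$time[i], day$boluses$dose_U[i],
                  label = paste0("bolus", i)))
  t0 <- min(0, day$cgm$time[1])
  if (is.null(t_end)) t_end <- max(day$cgm$time)
  scenario(t_end = t_end, t_start = t0, meals = meals, boluses = boluses,
           basal = day$basal, activity = day$activity)
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a virtual subject
#'
#' Draws a virtual subject by perturbing selected parameters of a population
#' parameter set with independent lognormal factors of unit mean and a given
#' coefficient of variation, emulating between-subject variability in
#' insulin sensitivity, glucose effectiveness, basal glycemia and the
#' exercise response.
#'
#' @param seed integer RNG seed; the subject is a deterministic function of
#'   it (the caller's RNG state is left untouched).
#' @param cv coefficient of variation of the lognormal perturbation factors
#'   (default 0.2).
#' @param perturb names of parameters to perturb (subset of the population
#'   set; default `p1`, `p3`, `Gb`, `b`, `q1`, `q2`).
#' @param base population `glucopa_params` (default set `"v1"`).
#' @return A `glucopa_subject`: list with `params` (the perturbed
#'   `glucopa_params`), `BW`, and `factors` (the drawn perturbations).
#' @export
generate_subject <- function(seed, cv = 0.2,
                             perturb = c("p1", "p3", "Gb", "b", "q1", "q2"),
                             base = default_parameters("v1")) {
  stopifnot(inherits(base, "glucopa_params"), cv >= 0)
  factors <- stats::setNames(rep(1, length(perturb)), perturb)
  if (cv > 0 && length(perturb) > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    factors <- with_seed(seed, stats::setNames(
      stats::rlnorm(length(perturb), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      perturb))
  }
  repl <- as.list(unlist(lapply(perturb, function(nm) base[[nm]])) * factors)
  names(repl) <- perturb
  params <- do.call(update_parameters, c(list(base), repl))
  structure(list(params = params, BW = params$BW, factors = factors,
                 seed = seed),
            class = "glucopa_subject")
}

#' Generate a synthetic recorded day with known ground truth
#'
#' Simulates a subject through a template scenario and emits the three
#' observation streams of a free-living recording: a noisy minute-resolution
#' accelerometer trace (rest background counts plus jitter around the
#' template bouts), CGM glucose on a 5-min grid with additive Gaussian
#' sensor noise clipped to the 40-400 mg/dl sensor range, and a logbook copy
#' of the template's meal and insulin events, optionally with seeded
#' misreporting. The noise-free truth (trajectory, parameters, per-meal
#' absorption parameters) is returned alongside but kept separate from the
#' observed `glucopa_day`.
#'
#' The truth trajectory is simulated against the noisy accelerometer trace
#' (a tracker measures the activity actually performed), so fitting against
#' the recorded counts is consistent with the generating model.
#'
#' @param subject a `glucopa_subject`.
#' @param template a `glucopa_scenario` spanning at most 24 h.
#' @param seed integer RNG seed for all noise streams.
#' @param cgm_noise_sd CGM sensor noise standard deviation, mg/dl.
#' @param ac_jitter_sd accelerometer jitter during bouts, counts/min.
#' @param rest_counts_max upper bound of the uniform rest background counts
#'   (kept far below the 1000 counts/min tracking threshold).
#' @param misreport optional list with elements `size_error_sd` (relative sd
#'   of the logged meal sizes) and/or `omit` (indices of meals to drop from
#'   the logbook).
#' @return A `glucopa_synthetic_day`: list with `day` (a `glucopa_day`) and
#'   `truth` (true parameters, scenario, noise-free trajectory and meal
#'   parameters).
#' @export
generate_day <- function(subject, template, seed, cgm_noise_sd = 10,
                         ac_jitter_sd = 100, rest_counts_max = 200,
                         misreport = NULL) {
  stopifnot(inherits(subject, "glucopa_subject"),
            inherits(template, "glucopa_scenario"))
  if (template$t_end - template$t_start > 1441)
    stop("the template scenario must span at most 24 h", call. = FALSE)
  tt <- seq(template$t_start, template$t_end - 1)
  base_counts <- ac_at(template$activity, tt)

  streams <- with_seed(seed, {
    rest <- stats::runif(length(tt), 0, rest_counts_max)
    jit <- stats::rnorm(length(tt), 0, ac_jitter_sd)
    counts <- ifelse(base_counts > 0, pmax(0, base_counts + jit), rest)
    cgm_eps <- stats::rnorm(length(seq(template$t_start, template$t_end, by = 5)))
    size_factors <- if (!is.null(misreport$size_error_sd))
      stats::rnorm(length(template$meals), 1, misreport$size_error_sd)
    else rep(1, length(template$meals))
    list(counts = counts, cgm_eps = cgm_eps, size_factors = size_factors)
  })

  trace <- data.frame(time = tt, counts = streams$counts)
  true_sc <- template
  true_sc$activity <- trace
  truth_sim <- simulate(true_sc, subject$params)

  cgm_times <- seq(template$t_start, template$t_end, by = 5)
  g_true <- glucose_at(truth_sim, cgm_times)
  g_obs <- g_true + cgm_noise_sd * streams$cgm_eps
  g_obs <- pmin(pmax(g_obs, 40), 400)

  meals <- data.frame(
    time = vapply(template$meals, `[[`, numeric(1), "t0"),
    cho_g = vapply(template$meals, `[[`, numeric(1), "D") / 1000 *
      pmax(0.1, streams$size_factors))
  if (!is.null(misreport$omit) && length(misreport$omit))
    meals <- meals[-misreport$omit, , drop = FALSE]
  boluses <- data.frame(
    time = vapply(template$boluses, `[[`, numeric(1), "t0"),
    dose_U = vapply(template$boluses, `[[`, numeric(1), "dose_U"))

  day <- recorded_day(
    cgm = data.frame(time = cgm_times, glucose = g_obs),
    activity = trace, meals = meals, boluses = boluses,
    basal = template$basal, BW = subject$params$BW)

  truth <- list(
    params = subject$params,
    scenario = true_sc,
    trajectory = truth_sim$trajectory,
    cgm_true = data.frame(time = cgm_times, glucose = g_true),
    meal_params = data.frame(
      f = vapply(template$meals, `[[`, numeric(1), "f"),
      tau_m = vapply(template$meals, `[[`, numeric(1), "tau_m")))
  structure(list(day = day, truth = truth, seed = seed),
            class = "glucopa_synthetic_day")
}
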