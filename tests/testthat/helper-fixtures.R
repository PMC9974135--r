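# shared fixtures: population parameters, a 24-h recorded-day template with
# three meals, meal boluses, two correction boluses and one afternoon
# activity bout, and small scenario builders used across tests

pop_params <- function() default_parameters("v1")

day_template <- function(with_activity = TRUE, t_end = 1440) {
  activity <- if (with_activity && t_end > 975)
    ac_trace_from_bouts(data.frame(start = 930, duration = 45,
                                   intensity = 55))
  meals <- list(meal_event("07:00", 40, f = 0.8, tau_m = 30, label = "breakfast"),
                meal_event("13:00", 60, f = 0.85, tau_m = 55, label = "lunch"),
                meal_event("19:00", 50, f = 0.9, tau_m = 45, label = "dinner"))
  boluses <- list(insulin_bolus("07:00", 4, label = "breakfast"),
                  insulin_bolus("10:30", 1.5, label = "correction1"),
                  insulin_bolus("13:00", 6, label = "lunch"),
                  insulin_bolus("19:00", 5, label = "dinner"),
                  insulin_bolus("22:00", 1.5, label = "correction2"))
  keep_m <- vapply(meals, function(m) m$t0 < t_end, logical(1))
  keep_b <- vapply(boluses, function(b) b$t0 < t_end, logical(1))
  scenario(t_end = t_end, meals = meals[keep_m], boluses = boluses[keep_b],
           basal = 0.8, activity = activity)
}

# a short scenario (a few hours) for fast solver tests
short_scenario <- function(t_end = 360, ac = NULL, meals = list(),
                           boluses = list()) {
  scenario(t_end = t_end, meals = meals, boluses = boluses, basal = 0.8,
           activity = ac)
}

# random but reproducible scenario for property suites
random_scenario <- function(seed, t_end = 720) {
  set.seed(seed)
  n_meal <- sample(0:2, 1)
  meals <- lapply(seq_len(n_meal), function(i)
    meal_event(runif(1, 30, t_end - 200), runif(1, 20, 80),
               f = runif(1, 0.5, 1), tau_m = runif(1, 20, 80)))
  n_bol <- sample(0:2, 1)
  boluses <- lapply(seq_len(n_bol), function(i)
    insulin_bolus(round(runif(1, 30, t_end - 120)), runif(1, 0.5, 5)))
  ac <- NULL
  if (runif(1) < 0.8) {
    start <- round(runif(1, 60, t_end - 200))
    ac <- ac_trace_from_bouts(data.frame(
      start = start, duration = round(runif(1, 20, 90)),
      intensity = runif(1, 25, 88)))
  }
  scenario(t_end = t_end, meals = meals, boluses = boluses,
           basal = round(runif(1, 0.5, 1.2), 2), activity = ac)
}
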