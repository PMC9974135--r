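# ---- internal bounded least-squares engine -------------------------------
#
# Parameters are fitted on a relative scale (value / start) so that the
# Levenberg-Marquardt steps are well conditioned across the very different
# magnitudes involved (p3 ~ 1e-5 vs Gb ~ 130). Bounds follow the fitting
# contract: p1, p3 in (0, 10x population], Gb in [70, 300] mg/dl, per-meal
# f in (0, 1], tau_m in [10, 240] min.

core_bounds <- function(nm, start) {
  switch(nm,
         p1 = c(1e-3 * start, 10 * start),
         p3 = c(1e-3 * start, 10 * start),
         Gb = c(70, 300),
         b  = c(1e-3 * start, 1e3 * start),
         qscale = c(1e-3, 1e3),
         c(1e-3 * start, 1e3 * start))
}

# build scaled start/bound/decoder for a day objective
make_day_objective <- function(day, params0, free, fit_meals, meal_init,
                               sim_control) {
  nmeal <- nrow(day$meals)
  fit_meals <- fit_meals && nmeal > 0
  start <- vapply(free, function(nm) params0[[nm]], numeric(1))
  names(start) <- free
  lower <- upper <- numeric(0)
  for (nm in free) {
    bb <- core_bounds(nm, start[[nm]])
    lower <- c(lower, bb[1] / start[[nm]])
    upper <- c(upper, bb[2] / start[[nm]])
  }
  par_names <- free
  mstart <- NULL
  if (fit_meals) {
    if (is.null(meal_init))
      meal_init <- data.frame(f = rep(0.9, nmeal), tau_m = rep(40, nmeal))
    mstart <- c(rbind(meal_init$f, meal_init$tau_m))
    for (i in seq_len(nmeal)) {
      lower <- c(lower, 0.02 / meal_init$f[i], 10 / meal_init$tau_m[i])
      upper <- c(upper, 1 / meal_init$f[i], 240 / meal_init$tau_m[i])
      par_names <- c(par_names, paste0(c("f", "tau_m"), i))
    }
  }
  start_all <- c(start, mstart)
  decode <- function(par_scaled) {
    vals <- par_scaled * start_all
    repl <- as.list(vals[seq_along(free)])
    names(repl) <- free
    params <- do.call(update_parameters, c(list(params0), repl))
    mp <- NULL
    if (fit_meals) {
      mv <- vals[-seq_along(free)]
      mp <- data.frame(f = mv[seq(1, length(mv), 2)],
                       tau_m = mv[seq(2, length(mv), 2)])
    } else if (nmeal > 0) {
      mp <- if (is.null(meal_init))
        data.frame(f = rep(0.9, nmeal), tau_m = rep(40, nmeal)) else meal_init
    }
    list(params = params, meal_params = mp)
  }
  obs <- day$cgm$glucose
  resid_fn <- function(par_scaled) {
    dec <- decode(par_scaled)
    sc <- day_to_scenario(day, dec$meal_params)
    sim <- do.call(simulate, c(list(sc, dec$params), sim_control))
    glucose_at(sim, day$cgm$time) - obs
  }
  list(par0 = rep(1, length(start_all)), lower = lower, upper = upper,
       par_names = par_names, decode = decode, resid_fn = resid_fn,
       start = start_all, fit_meals = fit_meals)
}

# fit each meal's (f, tau_m) on the window from its start to the next meal
# start (or day end), other meals and core parameters frozen; meals are
# updated sequentially so earlier fits inform later windows
fit_meal_windows <- function(day, params, meal_params, sim_control, maxiter) {
  t0s <- day$meals$time
  ends <- c(t0s[-1], max(day$cgm$time) + 1)
  for (i in seq_along(t0s)) {
    idx <- day$cgm$time >= t0s[i] & day$cgm$time < ends[i]
    if (sum(idx) < 4) next
    obs <- day$cgm$glucose[idx]
    start <- c(meal_params$f[i], meal_params$tau_m[i])
    resid_fn <- function(ps) {
      mp <- meal_params
      mp$f[i] <- ps[1] * start[1]
      mp$tau_m[i] <- ps[2] * start[2]
      sim <- do.call(simulate, c(list(day_to_scenario(day, mp), params),
                                 sim_control))
      glucose_at(sim, day$cgm$time[idx]) - obs
    }
    opt <- minpack.lm::nls.lm(
      par = c(1, 1), lower = c(0.02, 10) / start, upper = c(1, 240) / start,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, nprint = 0,
                                           epsfcn = 1e-8))
    meal_params$f[i] <- opt$par[1] * start[1]
    meal_params$tau_m[i] <- opt$par[2] * start[2]
  }
  meal_params
}

run_nlslm <- function(obj, par0 = NULL, maxiter = 60) {
  if (is.null(par0)) par0 <- obj$par0
  # epsfcn widens the finite-difference steps of the numeric Jacobian well
  # above the ODE-solver noise floor in the residuals
  minpack.lm::nls.lm(par = par0, lower = obj$lower, upper = obj$upper,
                     fn = obj$resid_fn,
                     control = minpack.lm::nls.lm.control(
                       maxiter = maxiter, nprint = 0, epsfcn = 1e-8,
                       ftol = 1e-12, ptol = 1e-12))
}

finish_fit <- function(day, obj, opt, config, seeds = NULL) {
  dec <- obj$decode(opt$par)
  res <- obj$resid_fn(opt$par)
  est <- opt$par * obj$start
  names(est) <- obj$par_names
  tolr <- 1e-6
  bounds <- data.frame(
    parameter = obj$par_names,
    value = est,
    lower = obj$lower * obj$start,
    upper = obj$upper * obj$start,
    at_lower = opt$par <= obj$lower * (1 + tolr),
    at_upper = opt$par >= obj$upper * (1 - tolr),
    row.names = NULL)
  structure(list(
    params = dec$params,
    estimates = est,
    meal_params = dec$meal_params,
    rss = sum(res^2),
    rmsd = rmsd(day$cgm$glucose + res, day$cgm$glucose),
    mard = mard(day$cgm$glucose + res, day$cgm$glucose),
    n_obs = length(res),
    residuals = data.frame(time = day$cgm$time,
                           observed = day$cgm$glucose,
                           model = day$cgm$glucose + res,
                           residual = res),
    bounds = bounds,
    converged = opt$info %in% 1:4,
    info = opt$info, message = opt$message, niter = opt$niter,
    rsstrace = opt$rsstrace,
    day = day, config = config, seeds = seeds),
    class = "glucopa_fit")
}

#' @export
print.glucopa_fit <- function(x, ...) {
  cat("<glucopa_fit>\n  estimates:\n")
  for (nm in names(x$estimates))
    cat(sprintf("    %-8s %.6g\n", nm, x$estimates[[nm]]))
  cat(sprintf("  RMSD %.2f mg/dl | MARD %.2f%% | n = %d | %s (%d iter)\n",
              x$rmsd, x$mard, x$n_obs,
              if (x$converged) "converged" else "NOT converged", x$niter))
  invisible(x)
}

#' Personalize the model on a recorded day
#'
#' Fits the subject-specific parameters — insulin action gain `p3`, glucose
#' effectiveness `p1`, basal glucose `Gb`, and per-meal absorption
#' parameters `(f, tau_m)` — by bounded least squares of the simulated
#' glucose against the CGM record. The basal insulin level is recomputed
#' from the day's basal infusion rate; all exercise-related parameters stay
#' at their population values. Residuals are evaluated at the CGM
#' timestamps, with model output linearly interpolated from the 1-min
#' simulation grid, and the objective is the unweighted sum of squared
#' glucose differences in mg/dl.
#'
#' @param day a `glucopa_day`.
#' @param params0 population `glucopa_params` used as starting point and for
#'   all frozen parameters.
#' @param config optional list: `free` (character, default
#'   `c("p1","p3","Gb")`), `fit_meals` (default `TRUE`), `meal_init`
#'   (data frame of per-meal starting `f`/`tau_m`), `maxiter` (default 100),
#'   `n_starts` (default 1; additional seeded lognormal multi-starts),
#'   `start_cv` (default 0.2), `seed` (default 1, used only when
#'   `n_starts > 1`), `sim` (list of [simulate()] arguments, e.g. tighter
#'   tolerances).
#' @return A `glucopa_fit` with fitted parameters, per-meal `(f, tau_m)`,
#'   residuals, RMSD (mg/dl), MARD (%), bound-hit flags and optimizer
#'   diagnostics. Non-convergence is flagged (`converged = FALSE`) and the
#'   best point found is returned.
#' @export
personalize <- function(day, params0, config = list()) {
  stopifnot(inherits(day, "glucopa_day"), inherits(params0, "glucopa_params"))
  cfg <- modifyList(list(free = c("p1", "p3", "Gb"), fit_meals = TRUE,
                         meal_init = NULL, maxiter = 100, n_starts = 1,
                         start_cv = 0.2, seed = 1, staged = TRUE,
                         sim = list(rtol = 1e-8, atol = 1e-10)),
                    config)
  if (nrow(day$cgm) < 10)
    stop("too few CGM points to fit (need at least 10)", call. = FALSE)
  params0 <- update_parameters(params0, BW = day$BW,
                               ub = basal_rate_at(list(basal = day$basal),
                                                  day$cgm$time[1]) )
  meal_init <- cfg$meal_init
  if (isTRUE(cfg$staged) && cfg$fit_meals && nrow(day$meals) > 0 &&
      length(cfg$free) > 0) {
    # stage A: basal level only (meal parameters held at their starting
    # values, so p1/p3 cannot absorb meal-shape mismatch); stage B: each
    # meal's (f, tau_m) on its own window (meal start to next meal start);
    # the joint fit then polishes everything from there
    free_A <- intersect(cfg$free, "Gb")
    if (length(free_A) == 0) free_A <- cfg$free
    objA <- make_day_objective(day, params0, free_A, FALSE, meal_init,
                               cfg$sim)
    optA <- run_nlslm(objA, maxiter = min(cfg$maxiter, 40))
    paramsA <- objA$decode(optA$par)$params
    if (is.null(meal_init))
      meal_init <- data.frame(f = rep(0.9, nrow(day$meals)),
                              tau_m = rep(40, nrow(day$meals)))
    meal_init <- fit_meal_windows(day, paramsA, meal_init, cfg$sim,
                                  maxiter = min(cfg$maxiter, 40))
    params0 <- paramsA
  }
  obj <- make_day_objective(day, params0, cfg$free, cfg$fit_meals,
                            meal_init, cfg$sim)
  seeds <- NULL
  opt <- run_nlslm(obj, maxiter = cfg$maxiter)
  if (cfg$n_starts > 1) {
    seeds <- cfg$seed + seq_len(cfg$n_starts - 1)
    sdlog <- sqrt(log(1 + cfg$start_cv^2))
    for (s in seeds) {
      par0 <- with_seed(s, stats::rlnorm(length(obj$par0), -sdlog^2 / 2, sdlog))
      par0 <- pmin(pmax(par0, obj$lower), obj$upper)
      opt2 <- run_nlslm(obj, par0 = par0, maxiter = cfg$maxiter)
      if (opt2$deviance < opt$deviance) opt <- opt2
    }
  }
  finish_fit(day, obj, opt, cfg, seeds = seeds)
}

#' Evaluate a personalized model on a second day
#'
#' Freezes the subject-level parameters `p1` and `p3` at their day-1
#' estimates and refits only the day-specific quantities — basal glucose
#' `Gb` and the per-meal absorption parameters — on the second day, to check
#' that the personalization generalizes to new scenarios.
#'
#' @param day2 a `glucopa_day`.
#' @param fit a `glucopa_fit` from [personalize()] containing `p1` and `p3`.
#' @param config optional list as in [personalize()] (the `free` entry is
#'   fixed to `"Gb"`).
#' @return A `glucopa_fit` for day 2.
#' @export
evaluate_second_day <- function(day2, fit, config = list()) {
  stopifnot(inherits(fit, "glucopa_fit"))
  if (!all(c("p1", "p3") %in% names(fit$estimates)))
    stop("'fit' must contain day-1 estimates of p1 and p3", call. = FALSE)
  config$free <- "Gb"
  personalize(day2, fit$params, config)
}

#' Re-estimate the exercise-response scale on population glucose data
#'
#' Refits the insulin-sensitivity rise gain `b` and the common scale of the
#' insulin-independent glucose-uptake rates `(q1, q2)` — with the ratio
#' `q1/q2` held fixed at its value in `params0`, which pins the steady-state
#' uptake gain — against a mean glucose trajectory from an exercise
#' scenario. All other parameters stay frozen. This is the adjustment used
#' when transferring the model to a study population whose exercise response
#' differs from the calibration population.
#'
#' @param glucose data frame with columns `time` (min) and `glucose`
#'   (mg/dl): the target mean glucose series.
#' @param sc the `glucopa_scenario` that produced the data; must contain an
#'   activity bout.
#' @param params0 starting `glucopa_params`.
#' @param config optional list: `maxiter` (default 100), `sim` (simulate
#'   arguments).
#' @return A `glucopa_fit` whose `estimates` contain `b` and `qscale`, and
#'   whose `params` carry the tuned `b`, `q1`, `q2` (ratio preserved).
#' @export
tune_validation_params <- function(glucose, sc, params0, config = list()) {
  stopifnot(is.data.frame(glucose), all(c("time", "glucose") %in% names(glucose)),
            inherits(sc, "glucopa_scenario"), inherits(params0, "glucopa_params"))
  if (is.null(sc$activity) || all(sc$activity$counts < params0$a_Y))
    stop("the scenario must contain an activity bout", call. = FALSE)
  cfg <- modifyList(list(maxiter = 100, sim = list(rtol = 1e-8, atol = 1e-10)),
                    config)
  q1_0 <- params0$q1; q2_0 <- params0$q2
  start <- c(b = params0$b, qscale = 1)
  lower <- c(core_bounds("b", params0$b)[1] / params0$b, 1e-3)
  upper <- c(core_bounds("b", params0$b)[2] / params0$b, 1e3)
  decode <- function(par_scaled) {
    vals <- par_scaled * start
    update_parameters(params0, b = vals[["b"]],
                      q1 = q1_0 * vals[["qscale"]],
                      q2 = q2_0 * vals[["qscale"]])
  }
  obs <- glucose$glucose
  resid_fn <- function(par_scaled) {
    sim <- do.call(simulate, c(list(sc, decode(par_scaled)), cfg$sim))
    glucose_at(sim, glucose$time) - obs
  }
  obj <- list(par0 = c(1, 1), lower = lower, upper = upper,
              par_names = c("b", "qscale"),
              decode = function(p) list(params = decode(p), meal_params = NULL),
              resid_fn = resid_fn, start = start, fit_meals = FALSE)
  opt <- run_nlslm(obj, maxiter = cfg$maxiter)
  day_like <- list(cgm = data.frame(time = glucose$time,
                                    glucose = glucose$glucose),
                   meals = data.frame())
  fit <- finish_fit(day_like, obj, opt, cfg)
  fit$estimates <- c(fit$estimates,
                     q1 = fit$params$q1, q2 = fit$params$q2)
  fit
}

#' Profile-likelihood confidence interval for a fitted parameter
#'
#' Scans the named parameter over a grid, re-optimizing all other free
#' parameters at each grid value, and reports the confidence interval where
#' the profiled sum of squares crosses the chi-square(1) threshold above the
#' minimum. Under Gaussian residuals with profiled variance the threshold is
#' `SSR_min * exp(qchisq(confidence, 1) / n)`. A side whose profile never
#' crosses the threshold within the grid is reported as non-identifiable in
#' that direction.
#'
#' @param fit a converged `glucopa_fit` from [personalize()].
#' @param param_name one of the fit's free core parameters (e.g. `"p3"`).
#' @param grid numeric vector of at least 3 parameter values to profile.
#' @param confidence confidence level (default 0.95).
#' @return List with `param`, `grid`, `profile` (SSR per grid value),
#'   `threshold`, `rss_min`, `ci` (lower/upper bounds, `NA` where
#'   non-identifiable) and `identifiable` (logical pair).
#' @export
profile_likelihood_ci <- function(fit, param_name, grid, confidence = 0.95) {
  stopifnot(inherits(fit, "glucopa_fit"))
  if (length(grid) < 3) stop("need at least 3 grid points", call. = FALSE)
  free0 <- fit$config$free
  if (!param_name %in% free0)
    stop("'", param_name, "' was not a free parameter of the fit", call. = FALSE)
  grid <- sort(grid)
  other <- setdiff(free0, param_name)
  prof <- vapply(grid, function(v) {
    params_v <- do.call(update_parameters,
                        c(list(fit$params), stats::setNames(list(v), param_name)))
    if (length(other) == 0 && !isTRUE(fit$config$fit_meals)) {
      obj <- make_day_objective(fit$day, params_v, free0[0], FALSE,
                                fit$meal_params, fit$config$sim)
      return(sum(obj$resid_fn(numeric(0))^2))
    }
    obj <- make_day_objective(fit$day, params_v, other, fit$config$fit_meals,
                              fit$meal_params, fit$config$sim)
    opt <- run_nlslm(obj, maxiter = fit$config$maxiter)
    opt$deviance
  }, numeric(1))
  rss_min <- min(c(fit$rss, prof))
  threshold <- rss_min * exp(stats::qchisq(confidence, df = 1) / fit$n_obs)
  inside <- prof <= threshold
  if (!any(inside)) inside[which.min(prof)] <- TRUE
  lo_idx <- min(which(inside)); hi_idx <- max(which(inside))
  ident <- c(lower = lo_idx > 1, upper = hi_idx < length(grid))
  ci <- c(lower = if (ident[["lower"]]) grid[lo_idx] else NA_real_,
          upper = if (ident[["upper"]]) grid[hi_idx] else NA_real_)
  list(param = param_name, grid = grid, profile = prof,
       threshold = threshold, rss_min = rss_min,
       ci = ci, identifiable = ident)
}
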