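# maximum number of meals the compiled RHS accepts (padded parameter block)
MAX_MEALS <- 24L

# flatten a glucopa_params object + meal list into the compiled parms vector
build_parms_vector <- function(params, meals) {
  if (length(meals) > MAX_MEALS)
    stop("at most ", MAX_MEALS, " meals per simulation are supported", call. = FALSE)
  fixed <- c(params$p1, params$p2, params$p3, params$p4, params$p5,
             params$Vg, params$BW, params$Gb,
             params$tau_AC, params$tau_Z, params$b,
             params$a_Y, params$n1, params$a_AC, params$n2,
             params$a_h, params$t_p, params$q5,
             params$q1, params$q2, params$q3l, params$q4l,
             params$q3h, params$q4h, params$q6,
             params$a_depl, params$b_depl, params$beta, params$rGPb,
             params$alpha,
             params$k1, params$k2, params$k3, params$k4, params$VI,
             params$Xb, params$Q1b, length(meals))
  mblock <- numeric(3L * MAX_MEALS)
  for (i in seq_along(meals)) {
    m <- meals[[i]]
    mblock[3L * (i - 1L) + 1:3] <- c(m$t0, m$f * m$D, m$tau_m)
  }
  c(fixed, mblock)
}

# step-function forcing matrices (AC counts and basal rate) spanning the horizon
build_forcings <- function(sc) {
  t0 <- sc$t_start; t1 <- sc$t_end
  if (is.null(sc$activity) || nrow(sc$activity) == 0L) {
    ac <- cbind(c(t0, t1), c(0, 0))
  } else {
    tr <- sc$activity
    tt <- tr$time; cc <- tr$counts
    # the trace is piecewise constant over [t, t+1); it ends 1 min after the
    # last sample, and is zero in gaps wider than 1 min
    gaps <- which(diff(tt) > 1 + 1e-9)
    if (length(gaps)) {
      tt <- c(tt, tt[gaps] + 1); cc <- c(cc, numeric(length(gaps)))
      o <- order(tt); tt <- tt[o]; cc <- cc[o]
    }
    tt <- c(tt, tt[length(tt)] + 1); cc <- c(cc, 0)
    if (tt[1] > t0) { tt <- c(t0, tt); cc <- c(0, cc) }
    keep <- tt <= t1
    tt <- tt[keep]; cc <- cc[keep]
    ac <- cbind(tt, cc)
  }
  ubr <- uU_per_min_from_U_per_h(sc$basal$rate_Uh)
  ubt <- sc$basal$time
  if (ubt[1] > t0) { ubt <- c(t0, ubt); ubr <- c(ubr[1], ubr) }
  keep <- ubt <= t1
  ub <- cbind(ubt[keep], ubr[keep])
  list(ac = ac, ub = ub)
}

#' Simulate a scenario
#'
#' Integrates the full model over a scenario with `deSolve::ode` (default
#' Dormand-Prince `"ode45"`) using the
#' package's compiled right-hand side. Accelerometer counts and the basal
#' infusion rate enter as piecewise-constant forcings; insulin boluses are
#' instantaneous additions to the first subcutaneous compartment handled as
#' solver events; meal glucose appearance is evaluated analytically inside
#' the right-hand side. The maximum internal step is capped (default 1 min)
#' so the solver cannot overstep the minute-resolution switching of the
#' activity input.
#'
#' @param sc a `glucopa_scenario`.
#' @param params a `glucopa_params` object. The basal insulin level (and so
#'   the remote-action constant `Xb`) is recomputed from the basal rate
#'   active at scenario start.
#' @param initial_state optional named state vector ([state_names()]);
#'   defaults to the basal steady state at the scenario-start basal rate,
#'   with all activity states at zero.
#' @param grid_step output grid spacing, min.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param hmax maximum internal step, min.
#' @param method integration method passed to `deSolve::ode`.
#' @return A `glucopa_sim` object; `$trajectory` is a data frame with the
#'   time grid, all states, glucose `G` (mg/dl), plasma insulin `I` (uU/ml),
#'   the production/uptake decomposition `GP`/`GU` (mg/kg/min), the inputs
#'   `Ra` (mg/min) and `AC` (counts/min), the active depletion time `tdepl`
#'   (min) and the basal rate `ub` (uU/min).
#' @export
simulate <- function(sc, params, initial_state = NULL, grid_step = 1,
                     rtol = 1e-8, atol = 1e-10, hmax = 1, method = "ode45") {
  stopifnot(inherits(sc, "glucopa_scenario"), inherits(params, "glucopa_params"))
  ub0 <- basal_rate_at(sc, sc$t_start)
  params <- update_parameters(params, ub = ub0)
  if (is.null(initial_state)) {
    y0 <- basal_steady_state(params)
  } else {
    if (is.null(names(initial_state))) names(initial_state) <- state_names()
    y0 <- initial_state[state_names()]
    if (any(is.na(y0))) stop("initial_state must contain all states", call. = FALSE)
  }

  times <- seq(sc$t_start, sc$t_end, by = grid_step)
  if (times[length(times)] < sc$t_end) times <- c(times, sc$t_end)
  fc <- build_forcings(sc)

  # the piecewise-constant forcings make the RHS discontinuous; restart the
  # solver at every forcing breakpoint (zero-valued events) and at boluses
  ac_jumps <- fc$ac[c(TRUE, diff(fc$ac[, 2]) != 0), 1]
  breaks <- unique(c(ac_jumps, fc$ub[, 1], sc$basal$time))
  ev <- data.frame(var = "x1", time = breaks, value = 0, method = "add")
  if (length(sc$boluses)) {
    bt <- vapply(sc$boluses, `[[`, numeric(1), "t0")
    bd <- vapply(sc$boluses, `[[`, numeric(1), "dose_U")
    ev <- rbind(ev, data.frame(var = "x1", time = bt,
                               value = uU_from_U(bd), method = "add"))
  }
  ev <- stats::aggregate(value ~ var + time + method, data = ev, FUN = sum)
  ev <- ev[order(ev$time), c("var", "time", "value", "method")]
  ev <- ev[ev$time >= sc$t_start & ev$time <= sc$t_end, ]
  times <- sort(unique(c(times, ev$time)))
  times <- times[times >= sc$t_start & times <= sc$t_end]
  parms <- build_parms_vector(params, sc$meals)
  out <- deSolve::ode(
    y = y0, times = times, func = "derivsglucopa", parms = parms,
    method = method,
    dllname = "glucopa", initfunc = "initglucopa", initforc = "forcglucopa",
    forcings = list(fc$ac, fc$ub),
    fcontrol = list(method = "constant", rule = 2, f = 0),
    nout = 7, outnames = c("G", "Ra", "AC", "GP", "GU", "tdepl", "ub"),
    rtol = rtol, atol = atol, hmax = hmax, maxsteps = 50000,
    events = if (is.null(ev)) NULL else list(data = ev))
  traj <- as.data.frame(out)
  if (any(!is.finite(as.matrix(traj)))) {
    bad <- which(!stats::complete.cases(traj) |
                   apply(!is.finite(as.matrix(traj)), 1, any))[1]
    stop("solver produced nonfinite values; last valid time = ",
         if (bad > 1) traj$time[bad - 1] else sc$t_start, " min", call. = FALSE)
  }
  # snap numerically tiny negatives (solver tolerance level) to zero
  svars <- state_names()
  for (v in svars) {
    neg <- traj[[v]] < 0 & traj[[v]] > -1e-7
    if (any(neg)) traj[[v]][neg] <- 0
  }
  structure(list(trajectory = traj, scenario = sc, params = params,
                 solver = list(method = method, rtol = rtol, atol = atol,
                               hmax = hmax, grid_step = grid_step)),
            class = "glucopa_sim")
}

#' @export
print.glucopa_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<glucopa_sim> %d time points over [%g, %g] min\n",
              nrow(tr), tr$time[1], tr$time[nrow(tr)]))
  cat(sprintf("  G: min %.1f, mean %.1f, max %.1f mg/dl\n",
              min(tr$G), mean(tr$G), max(tr$G)))
  invisible(x)
}

#' Input functions of a scenario
#'
#' Packages a scenario's exogenous signals as functions of time suitable for
#' [model_rhs()]: piecewise-constant accelerometer counts `AC(t)`, total meal
#' appearance `Ra(t)`, basal rate `ub(t)` and zero continuous correction
#' insulin `u(t)` (boluses are state jumps, not continuous inputs).
#'
#' @param sc a `glucopa_scenario`.
#' @return List of functions `AC`, `Ra`, `u`, `ub`.
#' @export
scenario_inputs <- function(sc) {
  force(sc)
  list(AC = function(t) ac_at(sc$activity, t),
       Ra = function(t) total_ra(t, sc$meals),
       u = function(t) numeric(length(t)),
       ub = function(t) basal_rate_at(sc, t))
}

#' Interpolate simulated glucose at arbitrary times
#'
#' @param sim a `glucopa_sim` object.
#' @param times times (min) at which to evaluate glucose.
#' @return Numeric vector of glucose values, mg/dl (linear interpolation of
#'   the output grid).
#' @export
glucose_at <- function(sim, times) {
  stats::approx(sim$trajectory$time, sim$trajectory$G, xout = times,
                rule = 2)$y
}
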