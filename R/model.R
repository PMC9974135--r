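#' Right-hand side of the full model ODE system
#'
#' Reference (R-level) implementation of the complete system of 14 ordinary
#' differential equations: the two-compartment glucose core with remote
#' insulin action, the subcutaneous insulin cascade, the filtered activity
#' intensity and its duration/count/high-intensity trackers, the
#' insulin-sensitivity elevation, the insulin-independent uptake and
#' production rates, and the depletion-driven production decline. The
#' compiled simulator in [simulate()] implements the same equations; this
#' function is the documented single-point evaluation used for fixed-point
#' checks, flux-conservation identities and as a building block for
#' independent integration oracles.
#'
#' @param t time, min.
#' @param state named numeric state vector in [state_names()] order.
#' @param params a `glucopa_params` object.
#' @param inputs list of input functions of time: `AC(t)` (counts/min),
#'   `Ra(t)` (mg/min), `u(t)` (uU/min, continuous correction insulin; bolus
#'   doses are state jumps, not part of `u`), `ub(t)` (uU/min). Missing
#'   entries default to zero functions.
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
model_rhs <- function(t, state, params, inputs = list()) {
  if (any(!is.finite(state)))
    stop("nonfinite state passed to model_rhs: ",
         paste(state_names()[!is.finite(state)], collapse = ", "),
         call. = FALSE)
  # note [[: `$` would partially match "u" against "ub"
  AC <- if (is.null(inputs[["AC"]])) 0 else inputs[["AC"]](t)
  Ra <- if (is.null(inputs[["Ra"]])) 0 else inputs[["Ra"]](t)
  u  <- if (is.null(inputs[["u"]]))  0 else inputs[["u"]](t)
  ub <- if (is.null(inputs[["ub"]])) 0 else inputs[["ub"]](t)

  s <- as.list(state)
  p <- params

  fAC <- transfer_function(AC, p$a_AC, p$n2)
  fh  <- transfer_function(AC, p$a_h, p$n2)
  fY  <- transfer_function(s$Y, p$a_Y, p$n1)

  q34 <- effective_q3_q4(s$th, p)
  tdepl <- depletion_time(s$PAint, s$tPA, p)
  fdepl <- if (tdepl <= 1e-9) as.numeric(s$tPA > 0) else
    transfer_function(s$tPA, tdepl, p$n1)
  rm_max <- p$beta * (q34[["q3"]] / q34[["q4"]] * s$Y + p$rGPb)

  dQ1 <- -(p$p1 + s$rGU - (s$rGP - s$rdepl) + (1 + s$Z) * s$X) * s$Q1 -
    p$p4 * s$Q1 + p$p5 * s$Q2 + (p$p1 + p$Xb) * p$Q1b + Ra / p$BW
  dQ2 <- p$p4 * s$Q1 - p$p5 * s$Q2
  dX  <- -p$p2 * s$X + p$p3 * s$I
  dI  <- p$k2 / (p$VI * p$BW) * s$x2 - p$k4 * s$I
  dx1 <- -p$k1 * s$x1 + u + ub
  dx2 <- p$k1 * s$x1 - (p$k2 + p$k3) * s$x2
  dY  <- (AC - s$Y) / p$tau_AC
  dtPA   <- fAC - (1 - fAC) * s$tPA
  dPAint <- fAC * AC - (1 - fAC) * s$PAint
  dth <- fh - (1 - fh) * p$q5 * s$th
  dZ  <- p$b * fY * s$Y - (1 - fY) * s$Z / p$tau_Z
  drGU <- p$q1 * fY * s$Y - p$q2 * s$rGU
  drGP <- q34[["q3"]] * fY * s$Y - q34[["q4"]] * s$rGP
  drdepl <- p$q6 * (fdepl * rm_max - s$rdepl)

  d <- c(Q1 = dQ1, Q2 = dQ2, X = dX, I = dI, x1 = dx1, x2 = dx2,
         Y = dY, tPA = dtPA, PAint = dPAint, th = dth, Z = dZ,
         rGU = drGU, rGP = drGP, rdepl = drdepl)
  if (any(!is.finite(d)))
    stop("nonfinite derivative for state(s): ",
         paste(names(d)[!is.finite(d)], collapse = ", "), call. = FALSE)
  d
}

#' Decompose the net glucose rate of change into production and uptake
#'
#' Separates the plasma-glucose balance into endogenous glucose production
#' (GP) and glucose uptake (GU), attributing the resting insulin and
#' glucose-effectiveness fluxes with the split fraction `alpha`:
#' \deqn{GP = (p1 + Xb) Q1b - \alpha [p1 + (1+Z) X] Q1 + (rGP - rdepl) Q1}
#' \deqn{GU = (1-\alpha) [p1 + (1+Z) X] Q1 + rGU \, Q1}
#' The decomposition satisfies the conservation identity
#' `GP - GU - p4*Q1 + p5*Q2 + Ra/BW = dQ1/dt` at any state.
#'
#' @param state named numeric state vector ([state_names()] order).
#' @param params a `glucopa_params` object.
#' @param Ra meal glucose appearance rate at the same instant, mg/min.
#' @return Named list with `GP`, `GU`, `Ra_scaled` (all mg/kg/min) and
#'   `exchange_net` (`p5*Q2 - p4*Q1`, mg/kg/min).
#' @export
decompose_fluxes <- function(state, params, Ra = 0) {
  s <- as.list(state)
  p <- params
  disposal <- (p$p1 + (1 + s$Z) * s$X) * s$Q1
  GP <- (p$p1 + p$Xb) * p$Q1b - p$alpha * disposal + (s$rGP - s$rdepl) * s$Q1
  GU <- (1 - p$alpha) * disposal + s$rGU * s$Q1
  list(GP = GP, GU = GU,
       Ra_scaled = Ra / p$BW,
       exchange_net = p$p5 * s$Q2 - p$p4 * s$Q1)
}
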