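#' Sigmoidal transfer function for exercise-regime switching
#'
#' Hill-type switch `f(x; p, n) = (x/p)^n / (1 + (x/p)^n)` used throughout the
#' model to turn activity processes on and off: detection of movement above a
#' count threshold, the transition from moderate- to high-intensity
#' metabolism, and the onset of glycogen depletion. The function is evaluated
#' in log space, `1 / (1 + exp(-n * (log(x) - log(p))))`, so that very steep
#' switches (the tracking exponent defaults to 100) do not overflow for large
#' counts.
#'
#' @param x nonnegative input (counts/min or min, depending on use).
#' @param p strictly positive threshold (same units as `x`).
#' @param n strictly positive steepness exponent.
#' @return Value(s) in `[0, 1)`; `0` at `x = 0` and `0.5` at `x = p`.
#' @examples
#' transfer_function(1500, 1500, 20)  # 0.5 at the threshold
#' transfer_function(3000, 1500, 20)  # ~1: clearly above threshold
#' @export
transfer_function <- function(x, p, n) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(!is.finite(n)) || any(n <= 0))
    stop("'p' and 'n' must be strictly positive", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    lx <- -n * (log(x[pos]) - log(p))
    out[pos] <- 1 / (1 + exp(pmin(lx, 745)))
  }
  out
}

#' Convert accelerometer counts to exercise intensity
#'
#' Linear conversion between accelerometer count (counts/min) and exercise
#' intensity expressed as a percentage of maximal oxygen uptake:
#' `%VO2max = 0.0135 * AC + 1.7228`. `ac_from_vo2max()` is the exact inverse.
#'
#' @param AC accelerometer counts per minute, nonnegative.
#' @return Intensity in %VO2max.
#' @examples
#' vo2max_from_ac(5800)   # ~80% VO2max, the high-intensity regime onset
#' ac_from_vo2max(30)     # counts corresponding to light activity
#' @export
vo2max_from_ac <- function(AC) {
  if (any(!is.finite(AC)) || any(AC < 0))
    stop("'AC' must be finite and nonnegative", call. = FALSE)
  0.0135 * AC + 1.7228
}

#' @rdname vo2max_from_ac
#' @param vo2max intensity in %VO2max, at least the resting intercept 1.7228.
#' @export
ac_from_vo2max <- function(vo2max) {
  if (any(!is.finite(vo2max)) || any(vo2max < 1.7228))
    stop("'vo2max' must be finite and at least the resting intercept 1.7228",
         call. = FALSE)
  (vo2max - 1.7228) / 0.0135
}

#' Time to glycogen depletion
#'
#' Depletion time decreases linearly with the average exercise intensity,
#' measured as the ratio of integrated accelerometer count to tracked
#' activity duration: `t_depl = -a_depl * (PAint / tPA) + b_depl`, floored at
#' zero. For very small tracked durations (`tPA < 0.5` min) the ratio is
#' numerically ill-defined and the intercept `b_depl` (the no-activity limit)
#' is returned.
#'
#' @param PAint integrated accelerometer count, counts.
#' @param tPA tracked activity duration, min.
#' @param params a `glucopa_params` object (fields `a_depl`, `b_depl`).
#' @return Depletion time in minutes, `>= 0`.
#' @export
depletion_time <- function(PAint, tPA, params) {
  ifelse(tPA < 0.5,
         params$b_depl,
         pmax(0, -params$a_depl * (PAint / tPA) + params$b_depl))
}

#' Effective glucose-production rate parameters
#'
#' Blends the insulin-independent glucose-production rise and decay rates
#' between their moderate- (`q3l`, `q4l`) and high-intensity (`q3h`, `q4h`)
#' values according to the time `th` spent at high intensity:
#' `q = (1 - f(th; t_p, n2)) * q_low + f(th; t_p, n2) * q_high`.
#'
#' @param th time at high intensity, min (nonnegative).
#' @param params a `glucopa_params` object.
#' @return Named numeric vector `c(q3 = ..., q4 = ...)`, both in 1/min.
#' @export
effective_q3_q4 <- function(th, params) {
  f <- transfer_function(th, params$t_p, params$n2)
  c(q3 = (1 - f) * params$q3l + f * params$q3h,
    q4 = (1 - f) * params$q4l + f * params$q4h)
}
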