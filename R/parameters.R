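#' Model parameters for the exercise-extended glucose-insulin model
#'
#' Constructs and validates the full parameter set of the model: the
#' two-compartment minimal-model core, subcutaneous insulin kinetics, meal
#' absorption scaling, and all physical-activity (PA) processes
#' (intensity filtering, insulin-sensitivity rise, insulin-independent
#' glucose uptake/production, glycogen depletion, high-intensity switching).
#'
#' Units follow the internal convention of the package: masses in mg (glucose)
#' and uU (insulin), concentrations in mg/dl and uU/ml, volumes in dl/kg and
#' ml/kg, times in minutes, activity in accelerometer counts/min.
#'
#' @param p1 glucose effectiveness, 1/min.
#' @param p2 remote-insulin-action decay rate, 1/min.
#' @param p3 insulin action gain, 1/min^2 per (uU/ml).
#' @param p4,p5 glucose inter-compartment exchange rates, 1/min.
#' @param Vg glucose distribution volume, dl/kg.
#' @param BW body weight, kg.
#' @param Gb basal plasma glucose concentration, mg/dl.
#' @param ub basal insulin infusion rate, uU/min.
#' @param tau_AC PA intensity filter delay, min.
#' @param tau_Z insulin-sensitivity recovery time constant, min.
#' @param b insulin-sensitivity rise gain, 1/count.
#' @param a_Y PA-onset intensity threshold, counts/min.
#' @param n1 onset-transfer exponent.
#' @param a_AC duration/count tracking threshold, counts/min.
#' @param n2 tracking and high-intensity transfer exponent.
#' @param a_h high-intensity AC threshold, counts/min.
#' @param t_p high-intensity dwell threshold, min.
#' @param q5 high-to-moderate switch-back delay rate, 1/min.
#' @param q1,q2 insulin-independent glucose-uptake rise/decay rates.
#' @param q3l,q4l insulin-independent glucose-production rise/decay rates in
#'   the moderate-intensity regime.
#' @param q3h,q4h the same rates in the high-intensity regime.
#' @param q6 depletion onset rate, 1/min (kept at or below 0.1).
#' @param a_depl depletion-time slope, min per (counts/min).
#' @param b_depl depletion-time intercept, min.
#' @param beta glycogenolysis fraction of net hepatic glucose production,
#'   in [0, 1].
#' @param rGPb basal resting glucose-production specific rate, 1/min; if
#'   `NULL` (default) it is derived as `(1 - alpha) * (p1 + Xb)`.
#' @param alpha resting-flux split fraction between production suppression and
#'   uptake, in [0, 1].
#' @param k1,k2,k3,k4 subcutaneous insulin kinetics rate constants, 1/min.
#' @param VI insulin distribution volume, ml/kg.
#'
#' @return An object of class `glucopa_params`: a named list of all parameters
#'   plus the derived basal quantities `Ib` (uU/ml), `Xb` (1/min) and
#'   `Q1b` (mg/kg).
#' @seealso [default_parameters()], [basal_steady_state()]
#' @export
model_parameters <- function(p1 = 0.02, p2 = 0.025, p3 = 1.3e-5,
                             p4 = 0.05, p5 = 0.05,
                             Vg = 1.6, BW = 50,
                             Gb = 130, ub = 0.8e6 / 60,
                             tau_AC = 5, tau_Z = 600, b = 2e-6,
                             a_Y = 1500, n1 = 20, a_AC = 1000, n2 = 100,
                             a_h = 5600, t_p = 2, q5 = 0.03,
                             q1 = 2.3e-7, q2 = 0.05,
                             q3l = 1.15e-7, q4l = 0.05,
                             q3h = 4.6e-7, q4h = 0.05,
                             q6 = 0.1,
                             a_depl = 0.036, b_depl = 305,
                             beta = 0.8, rGPb = NULL, alpha = 0.6,
                             k1 = 0.025, k2 = 0.018, k3 = 0.004, k4 = 0.15,
                             VI = 140) {
  p <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
            Vg = Vg, BW = BW, Gb = Gb, ub = ub,
            tau_AC = tau_AC, tau_Z = tau_Z, b = b,
            a_Y = a_Y, n1 = n1, a_AC = a_AC, n2 = n2,
            a_h = a_h, t_p = t_p, q5 = q5,
            q1 = q1, q2 = q2, q3l = q3l, q4l = q4l,
            q3h = q3h, q4h = q4h, q6 = q6,
            a_depl = a_depl, b_depl = b_depl,
            beta = beta, alpha = alpha,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4, VI = VI)
  pos <- c("p1", "p2", "p3", "p4", "p5", "Vg", "BW", "tau_AC", "tau_Z", "b",
           "a_Y", "n1", "a_AC", "n2", "a_h", "t_p", "q5",
           "q1", "q2", "q3l", "q4l", "q3h", "q4h", "q6",
           "a_depl", "b_depl", "k1", "k2", "k3", "k4", "VI")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (!is.finite(p$Gb) || p$Gb <= 0)
    stop("'Gb' must be strictly positive", call. = FALSE)
  if (!is.finite(p$ub) || p$ub < 0)
    stop("'ub' must be nonnegative", call. = FALSE)
  for (nm in c("alpha", "beta")) {
    v <- p[[nm]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  p <- derive_basal(p)
  if (is.null(rGPb)) {
    p$rGPb <- (1 - p$alpha) * (p$p1 + p$Xb)
  } else {
    if (!is.finite(rGPb) || rGPb <= 0)
      stop("'rGPb' must be strictly positive", call. = FALSE)
    p$rGPb <- rGPb
  }
  structure(p, class = "glucopa_params")
}

# basal plasma insulin, remote action and plasma glucose mass implied by the
# basal infusion rate (steady state of the SC insulin cascade)
derive_basal <- function(p) {
  p$Ib  <- p$k2 * p$ub / ((p$k2 + p$k3) * p$k4 * p$VI * p$BW)
  p$Xb  <- p$p3 / p$p2 * p$Ib
  p$Q1b <- p$Gb * p$Vg
  if (!is.finite(p$Q1b) || p$Q1b <= 0)
    stop("derived basal glucose mass Q1b is not positive", call. = FALSE)
  if (p$Ib < 0 || p$Xb < 0)
    stop("derived basal insulin quantities are negative", call. = FALSE)
  p
}

#' Update parameters and recompute derived basal quantities
#'
#' @param params a `glucopa_params` object.
#' @param ... named parameter values to replace.
#' @return A new `glucopa_params` object with `Ib`, `Xb`, `Q1b` (and a derived
#'   `rGPb`, unless it had been set explicitly) recomputed.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "glucopa_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  nms <- names(repl)
  explicit_rGPb <- "rGPb" %in% nms
  derived_rGPb <- isTRUE(all.equal(params$rGPb,
                                   (1 - params$alpha) * (params$p1 + params$Xb)))
  base <- unclass(params)
  base[c("Ib", "Xb", "Q1b")] <- NULL
  bad <- setdiff(nms, names(base))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  base[nms] <- repl
  if (!explicit_rGPb && derived_rGPb) base$rGPb <- NULL
  do.call(model_parameters, base)
}

#' Load a named parameter set
#'
#' Parameter sets are stored as flat JSON in the package's `extdata`
#' directory. The shipped file `parameter_sets_synthetic.json` provides three
#' named sets (`"v1"`, `"v2"`, `"v3"`) for a standard virtual subject; the
#' fixed structural constants (filter delays, thresholds, transfer exponents)
#' are shared, while the sets differ in insulin exposure and basal glycemia in
#' the way euglycemic/hyperglycemic clamp conditions differ. As documented in
#' the file's metadata block, the quantitative values are synthetic package
#' defaults chosen from physiological ranges, not measured constants.
#'
#' @param set name of the parameter set (`"v1"`, `"v2"` or `"v3"`).
#' @param file optional path to an alternative flat JSON parameter file; if it
#'   contains a top-level `sets` object the `set` selector applies, otherwise
#'   the file is read as a single flat name-value map.
#' @return A `glucopa_params` object.
#' @export
default_parameters <- function(set = c("v1", "v2", "v3"), file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "parameter_sets_synthetic.json",
                        package = "glucopa", mustWork = TRUE)
    set <- match.arg(set)
  }
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  vals <- if (!is.null(doc$sets)) {
    if (!set %in% names(doc$sets))
      stop("parameter file has no set named '", set, "'", call. = FALSE)
    doc$sets[[set]]
  } else doc
  vals <- vals[!vapply(vals, is.null, logical(1))]
  do.call(model_parameters, as.list(vals))
}

#' @export
print.glucopa_params <- function(x, ...) {
  cat("<glucopa_params>\n")
  cat(sprintf("  core: p1=%.4g p2=%.4g p3=%.4g p4=%.4g p5=%.4g Vg=%.3g BW=%.3g\n",
              x$p1, x$p2, x$p3, x$p4, x$p5, x$Vg, x$BW))
  cat(sprintf("  basal: Gb=%.4g mg/dl ub=%.4g uU/min -> Ib=%.4g uU/ml Xb=%.4g 1/min\n",
              x$Gb, x$ub, x$Ib, x$Xb))
  cat(sprintf("  PA: tau_AC=%.3g tau_Z=%.4g b=%.4g  q1=%.4g q2=%.4g q3l=%.4g q4l=%.4g\n",
              x$tau_AC, x$tau_Z, x$b, x$q1, x$q2, x$q3l, x$q4l))
  cat(sprintf("      q3h=%.4g q4h=%.4g q6=%.3g  depletion: a=%.3g b=%.4g beta=%.3g\n",
              x$q3h, x$q4h, x$q6, x$a_depl, x$b_depl, x$beta))
  cat(sprintf("  insulin SC: k1=%.3g k2=%.3g k3=%.3g k4=%.3g VI=%.4g\n",
              x$k1, x$k2, x$k3, x$k4, x$VI))
  invisible(x)
}

#' Names and order of the dynamic states
#'
#' The model integrates 14 states: plasma and remote glucose masses `Q1`,
#' `Q2` (mg/kg); remote insulin action `X` (1/min); plasma insulin `I`
#' (uU/ml); subcutaneous insulin masses `x1`, `x2` (uU); filtered PA
#' intensity `Y` (counts/min); tracked PA duration `tPA` (min); integrated
#' count `PAint` (counts); time at high intensity `th` (min);
#' insulin-sensitivity elevation `Z` (dimensionless); insulin-independent
#' uptake and production rates `rGU`, `rGP` (1/min); and the
#' depletion-driven production decline `rdepl` (1/min).
#'
#' @return Character vector of state names in integration order.
#' @export
state_names <- function() {
  c("Q1", "Q2", "X", "I", "x1", "x2",
    "Y", "tPA", "PAint", "th", "Z", "rGU", "rGP", "rdepl")
}

#' Basal (resting) steady state of the model
#'
#' Constructs the rest fixed point implied by a parameter set: subcutaneous
#' compartments at the basal-infusion steady state (`x1 = ub/k1`,
#' `x2 = ub/(k2+k3)`), plasma insulin at `Ib`, remote action at
#' `Xb = p3/p2 * Ib`, plasma glucose mass at `Q1b = Gb * Vg`, the remote
#' glucose compartment solved from its own equilibrium
#' (`Q2 = p4 * Q1b / p5`), and all activity states at zero. The model
#' right-hand side vanishes identically at this state when all exogenous
#' inputs are zero.
#'
#' @param params a `glucopa_params` object.
#' @param ub optional basal infusion rate (uU/min) overriding `params$ub`,
#'   e.g. the rate active at the start of a scenario.
#' @return Named numeric state vector (see [state_names()]).
#' @export
basal_steady_state <- function(params, ub = NULL) {
  stopifnot(inherits(params, "glucopa_params"))
  if (!is.null(ub)) params <- update_parameters(params, ub = ub)
  s <- c(Q1 = params$Q1b,
         Q2 = params$p4 * params$Q1b / params$p5,
         X = params$Xb,
         I = params$Ib,
         x1 = params$ub / params$k1,
         x2 = params$ub / (params$k2 + params$k3),
         Y = 0, tPA = 0, PAint = 0, th = 0, Z = 0,
         rGU = 0, rGP = 0, rdepl = 0)
  if (any(!is.finite(s)) || any(s < 0))
    stop("basal steady state contains nonpositive or nonfinite values; ",
         "check the parameter configuration", call. = FALSE)
  s[state_names()]
}

# convert a dose/rate between user units and internal units
uU_per_min_from_U_per_h <- function(x) x * 1e6 / 60
U_from_uU <- function(x) x / 1e6
uU_from_U <- function(x) x * 1e6
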