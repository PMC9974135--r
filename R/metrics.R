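#' Root mean square difference between model and observed glucose
#'
#' @param model model glucose series, mg/dl, aligned to the observation
#'   timestamps.
#' @param observed observed (CGM) glucose series, mg/dl, same length.
#' @return RMSD in mg/dl, computed over non-missing pairs.
#' @examples
#' rmsd(c(110, 90), c(100, 120))  # sqrt((100 + 900)/2)
#' @export
rmsd <- function(model, observed) {
  if (length(model) != length(observed))
    stop("'model' and 'observed' must have equal length after alignment",
         call. = FALSE)
  ok <- is.finite(model) & is.finite(observed)
  if (!any(ok)) stop("no overlapping non-missing observations", call. = FALSE)
  sqrt(mean((model[ok] - observed[ok])^2))
}

#' Mean absolute relative difference between model and observed glucose
#'
#' @inheritParams rmsd
#' @return MARD in percent, `100 * mean(|model - observed| / observed)`.
#' @examples
#' mard(c(90, 210), c(100, 200))  # 7.5
#' @export
mard <- function(model, observed) {
  if (length(model) != length(observed))
    stop("'model' and 'observed' must have equal length after alignment",
         call. = FALSE)
  ok <- is.finite(model) & is.finite(observed)
  if (!any(ok)) stop("no overlapping non-missing observations", call. = FALSE)
  if (any(observed[ok] <= 0))
    stop("observed glucose must be strictly positive for MARD", call. = FALSE)
  100 * mean(abs(model[ok] - observed[ok]) / observed[ok])
}

#' Glycemic summary statistics of a simulated trajectory
#'
#' Standard treatment-relevant summaries: fraction of time in the 70-180
#' mg/dl target range, below 70, above 180 (the three fractions sum to 1),
#' minimum/maximum/mean glucose, and mean nocturnal glucose over 00:00-06:00
#' clock time (times for which `time mod 1440 < 360`).
#'
#' @param sim a `glucopa_sim` object, or a data frame with columns `time`
#'   and `G`.
#' @return One-row data frame of summaries.
#' @export
glycemic_summary <- function(sim) {
  tr <- if (inherits(sim, "glucopa_sim")) sim$trajectory else sim
  stopifnot(all(c("time", "G") %in% names(tr)))
  g <- tr$G
  noct <- (tr$time %% 1440) < 360
  data.frame(
    time_in_range = mean(g >= 70 & g <= 180),
    time_below_70 = mean(g < 70),
    time_above_180 = mean(g > 180),
    min_G = min(g), max_G = max(g), mean_G = mean(g),
    mean_nocturnal_G = if (any(noct)) mean(g[noct]) else NA_real_)
}
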