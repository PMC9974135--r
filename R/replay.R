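#' Counterfactual modification of a scenario
#'
#' Describes one change to a recorded scenario for replay simulation.
#' Supported kinds:
#' \describe{
#'   \item{`scale_meal` / `set_meal`}{multiply a meal's carbohydrate content
#'     by `value`, or set it to `value` grams.}
#'   \item{`scale_bolus` / `set_bolus`}{multiply a bolus dose by `value`, or
#'     set it to `value` U.}
#'   \item{`shift_event`}{move a meal or bolus by `value` minutes.}
#'   \item{`set_pa_intensity`}{replace the counts of an activity session by
#'     the count corresponding to `value` %VO2max.}
#'   \item{`set_pa_duration`}{set the session duration to `value` minutes
#'     (extending with the session's mean counts or truncating); with
#'     `shift_post_meal = TRUE`, a meal logged within 15 min after the old
#'     session end (and its same-time bolus) moves with the new end.}
#'   \item{`move_pa`}{shift the whole session by `value` minutes.}
#'   \item{`suspend_basal`}{set the basal rate to zero over
#'     `value = c(start, end)` minutes.}
#' }
#'
#' Activity sessions are the contiguous segments of the trace at or above
#' the activity-onset threshold (1500 counts/min), addressed by `target` as
#' the segment index. Meals and boluses are addressed by label or by index.
#'
#' @param kind modification kind (see above).
#' @param target event selector: label (character) or index (integer); for
#'   activity kinds, the session index.
#' @param value magnitude (units depend on `kind`).
#' @param shift_post_meal for `set_pa_duration`: move the directly following
#'   meal to the new session end (default `FALSE`).
#' @return A `glucopa_mod` object.
#' @export
modification <- function(kind, target = 1, value = NULL,
                         shift_post_meal = FALSE) {
  kinds <- c("scale_meal", "set_meal", "scale_bolus", "set_bolus",
             "shift_event", "set_pa_intensity", "set_pa_duration",
             "move_pa", "suspend_basal")
  kind <- match.arg(kind, kinds)
  structure(list(kind = kind, target = target, value = value,
                 shift_post_meal = shift_post_meal), class = "glucopa_mod")
}

# resolve a selector to a unique index in a list of events with labels
resolve_event <- function(events, target, what) {
  if (is.character(target)) {
    labs <- vapply(events, function(e)
      if (is.null(e$label)) NA_character_ else e$label, character(1))
    idx <- which(labs == target)
  } else idx <- as.integer(target)
  if (length(idx) != 1 || is.na(idx) || idx < 1 || idx > length(events))
    stop("selector does not resolve to a unique ", what, call. = FALSE)
  idx
}

# contiguous above-threshold segments of an activity trace
pa_segments <- function(trace, a_Y = 1500) {
  if (is.null(trace) || nrow(trace) == 0) return(list())
  on <- trace$counts >= a_Y
  if (!any(on)) return(list())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(k) seq(starts[k], ends[k]))
}

#' Apply counterfactual modifications to a scenario
#'
#' Returns a new scenario with the requested modifications applied; the
#' input scenario is left untouched and the modification log is attached as
#' attribute `"modifications"`. The modified scenario is re-validated.
#'
#' @param sc a `glucopa_scenario`.
#' @param mods a single [modification()] or a list of them, applied in
#'   order.
#' @param a_Y activity-onset threshold used for session detection,
#'   counts/min.
#' @return A modified `glucopa_scenario`.
#' @export
apply_modifications <- function(sc, mods, a_Y = 1500) {
  stopifnot(inherits(sc, "glucopa_scenario"))
  if (inherits(mods, "glucopa_mod")) mods <- list(mods)
  stopifnot(all(vapply(mods, inherits, logical(1), "glucopa_mod")))
  out <- sc
  for (m in mods) out <- apply_one_mod(out, m, a_Y)
  # re-validate through the constructor
  res <- scenario(t_end = out$t_end, t_start = out$t_start, meals = out$meals,
                  boluses = out$boluses, basal = out$basal,
                  activity = out$activity)
  attr(res, "modifications") <- mods
  res
}

apply_one_mod <- function(sc, m, a_Y) {
  k <- m$kind
  if (k %in% c("scale_meal", "set_meal")) {
    i <- resolve_event(sc$meals, m$target, "meal")
    if (k == "scale_meal") sc$meals[[i]]$D <- sc$meals[[i]]$D * m$value
    else sc$meals[[i]]$D <- m$value * 1000
    if (sc$meals[[i]]$D <= 0) stop("modified meal size must be positive", call. = FALSE)
  } else if (k %in% c("scale_bolus", "set_bolus")) {
    i <- resolve_event(sc$boluses, m$target, "bolus")
    sc$boluses[[i]]$dose_U <- if (k == "scale_bolus")
      sc$boluses[[i]]$dose_U * m$value else m$value
    if (sc$boluses[[i]]$dose_U < 0) stop("dose must be nonnegative", call. = FALSE)
  } else if (k == "shift_event") {
    labs_m <- vapply(sc$meals, function(e)
      if (is.null(e$label)) NA_character_ else e$label, character(1))
    if (is.character(m$target) && m$target %in% labs_m) {
      i <- resolve_event(sc$meals, m$target, "meal")
      sc$meals[[i]]$t0 <- sc$meals[[i]]$t0 + m$value
    } else {
      i <- resolve_event(sc$boluses, m$target, "bolus")
      sc$boluses[[i]]$t0 <- sc$boluses[[i]]$t0 + m$value
    }
  } else if (k == "suspend_basal") {
    stopifnot(length(m$value) == 2)
    bs <- sc$basal
    rate_before <- bs$rate_Uh[max(findInterval(m$value[2], bs$time), 1)]
    bs <- bs[bs$time < m$value[1] | bs$time > m$value[2], , drop = FALSE]
    bs <- rbind(bs, data.frame(time = m$value[1], rate_Uh = 0),
                data.frame(time = m$value[2], rate_Uh = rate_before))
    sc$basal <- bs[order(bs$time), ]
  } else {
    # activity-session modifications
    if (is.null(sc$activity))
      stop("scenario has no activity to modify", call. = FALSE)
    segs <- pa_segments(sc$activity, a_Y)
    if (length(segs) == 0) stop("no activity session found", call. = FALSE)
    si <- as.integer(m$target)
    if (si < 1 || si > length(segs))
      stop("selector does not resolve to a unique activity session", call. = FALSE)
    idx <- segs[[si]]
    tr <- sc$activity
    if (k == "set_pa_intensity") {
      tr$counts[idx] <- ac_from_vo2max(m$value)
    } else if (k == "set_pa_duration") {
      t_start <- tr$time[idx[1]]
      old_end <- tr$time[idx[length(idx)]] + 1
      new_end <- t_start + m$value
      mean_counts <- mean(tr$counts[idx])
      keep <- tr$time < t_start | tr$time >= old_end
      seg_new <- data.frame(time = seq(t_start, new_end - 1),
                            counts = mean_counts)
      seg_old <- tr[idx, , drop = FALSE]
      seg_old <- seg_old[seg_old$time < new_end, , drop = FALSE]
      seg_new$counts[seq_len(nrow(seg_old))] <- seg_old$counts
      rest <- tr[keep & !(tr$time >= t_start & tr$time < new_end), , drop = FALSE]
      tr <- rbind(rest, seg_new)
      tr <- tr[order(tr$time), ]
      if (isTRUE(m$shift_post_meal)) {
        delta <- new_end - old_end
        for (i in seq_along(sc$meals)) {
          if (sc$meals[[i]]$t0 >= old_end && sc$meals[[i]]$t0 <= old_end + 15) {
            t_old_meal <- sc$meals[[i]]$t0
            sc$meals[[i]]$t0 <- sc$meals[[i]]$t0 + delta
            for (j in seq_along(sc$boluses))
              if (abs(sc$boluses[[j]]$t0 - t_old_meal) < 1e-9)
                sc$boluses[[j]]$t0 <- sc$boluses[[j]]$t0 + delta
          }
        }
      }
    } else if (k == "move_pa") {
      seg <- tr[idx, , drop = FALSE]
      tr$counts[idx] <- 0
      seg$time <- seg$time + m$value
      tr <- tr[!(tr$time %in% seg$time), , drop = FALSE]
      tr <- rbind(tr, seg)
      tr <- tr[order(tr$time), ]
    }
    sc$activity <- tr
  }
  sc
}

#' Replay a personalized day under counterfactual inputs
#'
#' Simulates the recorded day under the personalized model (the baseline)
#' and under one or more counterfactual input modifications, all from the
#' identical initial state — the basal steady state at the fitted basal
#' glucose — and with identical solver settings, and reports paired
#' treatment-relevant summaries.
#'
#' @param day the recorded `glucopa_day` the fit was obtained on.
#' @param fit the `glucopa_fit` personalizing the model to this subject.
#' @param mods a list of [modification()]s defining one counterfactual arm,
#'   or a named list of such lists defining several arms.
#' @param ... further arguments passed to [simulate()] (all arms share
#'   them).
#' @return A `glucopa_replay`: list with `baseline` and `arms` (named list
#'   of `glucopa_sim`), and `summary`, a data frame of [glycemic_summary()]
#'   rows for the baseline and every arm.
#' @export
replay_compare <- function(day, fit, mods, ...) {
  stopifnot(inherits(day, "glucopa_day"), inherits(fit, "glucopa_fit"))
  if (length(mods) > 0 && inherits(mods[[1]], "glucopa_mod"))
    mods <- list(counterfactual = mods)
  if (length(mods) > 0 && is.null(names(mods)))
    names(mods) <- paste0("arm", seq_along(mods))
  sc0 <- day_to_scenario(day, fit$meal_params)
  y0 <- basal_steady_state(fit$params,
                           ub = basal_rate_at(sc0, sc0$t_start))
  base_sim <- simulate(sc0, fit$params, initial_state = y0, ...)
  arms <- list(); failures <- character(0)
  for (nm in names(mods)) {
    arms[[nm]] <- tryCatch({
      sc_m <- apply_modifications(sc0, mods[[nm]], a_Y = fit$params$a_Y)
      simulate(sc_m, fit$params, initial_state = y0, ...)
    }, error = function(e) {
      failures <<- c(failures, nm)
      warning("replay arm '", nm, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(arms, is.null, logical(1))
  summ <- do.call(rbind, c(list(cbind(arm = "baseline",
                                      glycemic_summary(base_sim))),
                           lapply(names(arms)[ok], function(nm)
                             cbind(arm = nm, glycemic_summary(arms[[nm]])))))
  structure(list(baseline = base_sim, arms = arms[ok], summary = summ,
                 failed_arms = failures, mods = mods),
            class = "glucopa_replay")
}

#' @export
print.glucopa_replay <- function(x, ...) {
  cat("<glucopa_replay>\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (length(x$failed_arms))
    cat("  failed arms:", paste(x$failed_arms, collapse = ", "), "\n")
  invisible(x)
}
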