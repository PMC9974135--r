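# independent fixed-step classical RK4 integrator built directly on the
# R-level model_rhs(); shares no integration code with simulate()'s
# deSolve/compiled path

rk4_simulate <- function(sc, params, h = 0.01, grid_step = 1,
                         initial_state = NULL) {
  ub_fun <- scenario_inputs(sc)$ub
  params <- update_parameters(params, ub = ub_fun(sc$t_start))
  inputs <- scenario_inputs(sc)
  y <- if (is.null(initial_state)) basal_steady_state(params) else initial_state
  out_times <- seq(sc$t_start, sc$t_end, by = grid_step)
  bt <- vapply(sc$boluses, `[[`, numeric(1), "t0")
  bd <- vapply(sc$boluses, `[[`, numeric(1), "dose_U")
  out <- matrix(NA_real_, nrow = length(out_times), ncol = length(y),
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  for (k in seq_len(length(out_times) - 1)) {
    t0 <- out_times[k]; t1 <- out_times[k + 1]
    hit <- which(abs(bt - t0) < 1e-9)
    if (length(hit)) y[["x1"]] <- y[["x1"]] + sum(bd[hit]) * 1e6
    nstep <- max(1L, round((t1 - t0) / h))
    hh <- (t1 - t0) / nstep
    tt <- t0
    for (s in seq_len(nstep)) {
      k1 <- model_rhs(tt, y, params, inputs)
      k2 <- model_rhs(tt + hh / 2, y + hh / 2 * k1, params, inputs)
      k3 <- model_rhs(tt + hh / 2, y + hh / 2 * k2, params, inputs)
      k4 <- model_rhs(tt + hh, y + hh * k3, params, inputs)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + hh
    }
    out[k + 1, ] <- y
  }
  df <- as.data.frame(out)
  df$time <- out_times
  df$G <- df$Q1 / params$Vg
  df
}

# independent two-compartment minimal-model RHS (no activity extension),
# used to check that the full RHS reduces to it when all PA states vanish
minimal_model_dQ1 <- function(state, params, Ra) {
  with(as.list(state), {
    -(params$p1 + X) * Q1 - params$p4 * Q1 + params$p5 * Q2 +
      (params$p1 + params$Xb) * params$Q1b + Ra / params$BW
  })
}
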