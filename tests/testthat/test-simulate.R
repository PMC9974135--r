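test_that("an empty scenario stays at basal glucose for 48 h", {
  p <- pop_params()
  sim <- simulate(scenario(t_end = 2880, basal = 0.8), p)
  expect_lt(max(abs(sim$trajectory$G - p$Gb)), 1e-6 * p$Gb)
})

test_that("linear activity subsystems match their closed forms under constant counts", {
  p <- pop_params()
  AC <- 4000  # above a_Y and a_AC, below the high-intensity threshold
  tr <- data.frame(time = 0:239, counts = AC)
  sc <- short_scenario(t_end = 120, ac = tr)

  # intensity filter from rest: Y(t) = AC (1 - exp(-t/tau_AC))
  sim <- simulate(sc, p)
  tt <- sim$trajectory$time[-1]
  Yexp <- AC * (1 - exp(-tt / p$tau_AC))
  expect_lt(max(abs(sim$trajectory$Y[-1] - Yexp) / Yexp), 1e-6)

  # uptake/production rates with Y pinned at AC from the start:
  # r(t) = (gain/decay) AC (1 - exp(-decay t))
  y0 <- basal_steady_state(p)
  y0[["Y"]] <- AC
  sim2 <- simulate(sc, p, initial_state = y0)
  rGUexp <- p$q1 / p$q2 * AC * (1 - exp(-p$q2 * tt))
  rGPexp <- p$q3l / p$q4l * AC * (1 - exp(-p$q4l * tt))
  expect_lt(max(abs(sim2$trajectory$rGU[-1] - rGUexp) / rGUexp), 1e-6)
  expect_lt(max(abs(sim2$trajectory$rGP[-1] - rGPexp) / rGPexp), 1e-6)

  # sensitivity elevation decays with tau_Z once the counts stop
  y1 <- basal_steady_state(p)
  y1[["Z"]] <- 0.8
  sim3 <- simulate(short_scenario(t_end = 300), p, initial_state = y1)
  g <- sim3$trajectory
  Zexp <- 0.8 * exp(-g$time / p$tau_Z)
  expect_lt(max(abs(g$Z - Zexp) / Zexp), 1e-6)
})

test_that("flux columns satisfy the conservation identity on the output grid", {
  p <- pop_params()
  sim <- simulate(day_template(t_end = 1100), p)
  tr <- sim$trajectory
  for (i in seq(1, nrow(tr), by = 37)) {
    s <- unlist(tr[i, state_names()])
    d <- model_rhs(tr$time[i], s, sim$params,
                   list(Ra = function(t) tr$Ra[i]))
    expect_equal(tr$GP[i] - tr$GU[i] - p$p4 * tr$Q1[i] + p$p5 * tr$Q2[i] +
                   tr$Ra[i] / p$BW,
                 d[["Q1"]], tolerance = 1e-9)
  }
})

test_that("adaptive solution matches the independent RK4 oracle on a mixed scenario", {
  p <- pop_params()
  sc <- scenario(t_end = 300,
                 meals = list(meal_event(30, 50, f = 0.85, tau_m = 45)),
                 boluses = list(insulin_bolus(30, 3)),
                 basal = 0.8,
                 activity = ac_trace_from_bouts(
                   data.frame(start = 120, duration = 45, intensity = 65)))
  sim <- simulate(sc, p)
  rk <- rk4_simulate(sc, p, h = 0.01)
  g <- sim$trajectory$G[match(rk$time, sim$trajectory$time)]
  expect_lt(max(abs(g - rk$G)), 0.5)
  expect_lt(max(abs(g - rk$G)), 0.01)  # in practice far tighter
})

test_that("halving solver tolerances leaves glucose unchanged to 0.01 mg/dl", {
  p <- pop_params()
  sc <- day_template(t_end = 720)
  s1 <- simulate(sc, p, rtol = 1e-8, atol = 1e-10)
  s2 <- simulate(sc, p, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(s1$trajectory$G - s2$trajectory$G)), 0.01)
})

test_that("splitting a simulation at an interior time and chaining reproduces it", {
  p <- pop_params()
  sc <- day_template(t_end = 1100)  # breakfast, lunch, corrections, bout
  full <- simulate(sc, p)
  split_t <- 953  # mid-bout, between events
  bt <- vapply(sc$boluses, `[[`, numeric(1), "t0")
  sc1 <- scenario(t_end = split_t, meals = sc$meals,
                  boluses = sc$boluses[bt <= split_t],
                  basal = 0.8, activity = sc$activity)
  half1 <- simulate(sc1, p)
  y_mid <- unlist(half1$trajectory[half1$trajectory$time == split_t,
                                   state_names()])
  # second half keeps original event coordinates; ongoing meals carry over
  sc2 <- scenario(t_end = 1100, t_start = split_t, meals = sc$meals,
                  boluses = sc$boluses[bt > split_t],
                  basal = 0.8, activity = sc$activity)
  half2 <- simulate(sc2, p, initial_state = y_mid)
  tt <- full$trajectory$time[full$trajectory$time >= split_t]
  g_full <- full$trajectory$G[match(tt, full$trajectory$time)]
  g_chain <- half2$trajectory$G[match(tt, half2$trajectory$time)]
  expect_lt(max(abs(g_full - g_chain)), 1e-4)
})

test_that("states stay nonnegative across a randomized scenario suite", {
  p <- pop_params()
  for (seed in 1:8) {
    sc <- random_scenario(seed)
    tr <- simulate(sc, p)$trajectory
    expect_true(all(as.matrix(tr[state_names()]) >= 0),
                label = paste("seed", seed))
    expect_true(all(tr$G > 0))
  }
})

test_that("meal count limits and solver failure surface as errors", {
  p <- pop_params()
  too_many <- lapply(seq_len(25), function(i) meal_event(10 + i, 10))
  sc <- scenario(t_end = 200, meals = too_many)
  expect_error(simulate(sc, p), "at most")
})
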