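test_that("meal appearance has the gamma shape with maximum at tau_m", {
  m <- meal_event(100, 75, f = 0.8, tau_m = 105)
  expect_equal(meal_ra(100, m), 0)
  expect_equal(meal_ra(50, m), 0)
  # time of maximum equals the time constant
  opt <- optimize(function(t) meal_ra(t, m), c(100, 800), maximum = TRUE)
  expect_equal(opt$maximum - 100, 105, tolerance = 1e-3)
  # the kernel integrates to the absorbed fraction of the load
  igr <- integrate(function(t) meal_ra(t, m), 100, 100 + 40 * 105,
                   rel.tol = 1e-8, subdivisions = 1000L)
  expect_equal(igr$value, 0.8 * 75 * 1000, tolerance = 1e-3 * 0.8 * 75000)
})

test_that("total appearance superposes per-meal kernels with their own parameters", {
  expect_equal(total_ra(c(0, 50, 100), list()), c(0, 0, 0))
  m1 <- meal_event(60, 50, f = 0.9, tau_m = 40)
  expect_equal(total_ra(130, list(m1)), meal_ra(130, m1))
  # two identical meals 1 min apart equal the shifted sum
  m2 <- meal_event(61, 50, f = 0.9, tau_m = 40)
  tt <- seq(0, 400, 7)
  expect_equal(total_ra(tt, list(m1, m2)),
               meal_ra(tt, m1) + meal_ra(tt, m2))
  # superposition is nonnegative and vanishes before the first meal
  expect_true(all(total_ra(tt, list(m1, m2)) >= 0))
  expect_true(all(total_ra(tt[tt < 60], list(m1, m2)) == 0))
})

test_that("bout lists convert to count traces through the intensity line", {
  tr <- ac_trace_from_bouts(data.frame(start = 0, duration = 30,
                                       intensity = 80))
  expect_equal(nrow(tr), 30)
  expect_equal(unique(tr$counts), (80 - 1.7228) / 0.0135, tolerance = 1e-9)
  expect_equal(unique(tr$counts), 5798.3, tolerance = 1e-4)
  tr30 <- ac_trace_from_bouts(data.frame(start = 10, duration = 5,
                                         intensity = 30))
  expect_equal(max(tr30$counts), 2094.607, tolerance = 1e-3)
  expect_equal(tr30$counts[tr30$time < 10], rep(0, 10))
  empty <- ac_trace_from_bouts(list(), t_end = 10)
  expect_true(all(empty$counts == 0))
  expect_error(ac_trace_from_bouts(data.frame(start = c(0, 10),
                                              duration = c(20, 10),
                                              intensity = c(50, 50))),
               "overlap")
})

test_that("scenario validation enforces horizon, ordering and basal uniqueness", {
  expect_error(scenario(t_end = 100,
                        meals = list(meal_event(200, 50))),
               "horizon")
  expect_error(scenario(t_end = 100,
                        basal = data.frame(time = c(0, 0),
                                           rate_Uh = c(0.8, 1))),
               "strictly increasing")
  sc <- scenario(t_end = 1440,
                 meals = list(meal_event("13:00", 60), meal_event("07:00", 40)))
  # meals are sorted by time and clock strings parse to minutes
  expect_equal(vapply(sc$meals, `[[`, numeric(1), "t0"), c(420, 780))
  expect_error(meal_event(10, -5), "positive")
  expect_error(meal_event(10, 50, f = 1.2), "f")
  expect_error(insulin_bolus(10, -1), "nonnegative")
})

test_that("activity traces round-trip through CSV exactly", {
  tr <- ac_trace_from_bouts(data.frame(start = 3, duration = 17,
                                       intensity = 62.5), t_end = 40)
  path <- tempfile(fileext = ".csv")
  write_timeseries_csv(tr, path)
  back <- read_timeseries_csv(path, "activity")
  expect_equal(back$time, tr$time)
  expect_equal(back$counts, tr$counts, tolerance = 1e-12)
})

test_that("standard day scenarios place meals, boluses and the bout as specified", {
  sc <- build_standard_day("none")
  expect_equal(length(sc$meals), 3)
  expect_equal(vapply(sc$meals, `[[`, numeric(1), "t0"), c(420, 780, 1140))
  expect_equal(vapply(sc$meals, `[[`, numeric(1), "D") / 1000, c(40, 60, 50))
  expect_equal(vapply(sc$boluses, `[[`, numeric(1), "dose_U"), c(4, 6, 5))
  expect_null(sc$activity)
  sc2 <- build_standard_day("afternoon", 60, 180)
  expect_equal(sum(sc2$activity$counts > 0), 180)
  expect_equal(min(sc2$activity$time[sc2$activity$counts > 0]), 930)
  # a bout running over a meal is rejected
  expect_error(build_standard_day("afternoon", 60, 300), "overlaps a meal")
})
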