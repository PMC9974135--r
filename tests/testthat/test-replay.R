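# a quick personalized fit on a noise-free synthetic day, reused across
# replay tests (cached in the test environment)
replay_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      subj <- generate_subject(77, cv = 0.1, perturb = c("p1", "p3", "Gb"))
      sd1 <- generate_day(subj, day_template(), seed = 70, cgm_noise_sd = 0)
      fit <- personalize(sd1$day, pop_params())
      cache <<- list(day = sd1$day, fit = fit, subj = subj)
    }
    cache
  }
})

test_that("scenario modifications act on the addressed events only", {
  sc <- day_template()
  # identity scaling leaves the scenario unchanged
  sc_id <- apply_modifications(sc, modification("scale_meal", "lunch", 1.0))
  expect_equal(sc_id$meals, sc$meals)
  sc_l <- apply_modifications(sc, modification("scale_meal", "lunch", 1.5))
  expect_equal(sc_l$meals[[2]]$D, 1.5 * sc$meals[[2]]$D)
  expect_equal(sc_l$meals[[1]]$D, sc$meals[[1]]$D)
  sc_b <- apply_modifications(sc, modification("set_bolus", "lunch", 3))
  expect_equal(sc_b$boluses[[3]]$dose_U, 3)
  # intensity change rewrites the session counts through the conversion line
  sc_i <- apply_modifications(sc, modification("set_pa_intensity", 1, 40))
  seg <- sc_i$activity$counts[sc_i$activity$counts >= 1500]
  expect_equal(unique(seg), ac_from_vo2max(40))
  # basal suspension inserts a zero-rate window and restores the old rate
  sc_s <- apply_modifications(sc, modification("suspend_basal",
                                               value = c(930, 990)))
  expect_equal(basal_rate_at(sc_s, 960), 0)
  expect_equal(basal_rate_at(sc_s, 1000), basal_rate_at(sc, 1000))
  expect_error(apply_modifications(sc, modification("scale_meal", "supper", 2)),
               "unique meal")
})

test_that("extending an activity session can carry the following meal with it", {
  sc <- day_template()
  # a meal right after the session end (975): dinner is at 1140, so place a
  # snack directly post-exercise for this test
  sc2 <- scenario(t_end = 1440, meals = c(sc$meals,
                    list(meal_event(980, 20, label = "snack"))),
                  boluses = sc$boluses, basal = 0.8, activity = sc$activity)
  mod <- modification("set_pa_duration", 1, 85, shift_post_meal = TRUE)
  sc3 <- apply_modifications(sc2, mod)
  expect_equal(sum(sc3$activity$counts >= 1500), 85)
  snack <- sc3$meals[[which(vapply(sc3$meals, function(m)
    identical(m$label, "snack"), logical(1)))]]
  expect_equal(snack$t0, 980 + 40)  # moved by the 40-min extension
  # shortening truncates the session
  sc4 <- apply_modifications(sc2, modification("set_pa_duration", 1, 20))
  expect_equal(sum(sc4$activity$counts >= 1500), 20)
})

test_that("identity replay reproduces the baseline bit for bit", {
  fx <- replay_fixture()
  rep <- replay_compare(fx$day, fx$fit, list(identity = list()))
  expect_identical(rep$arms$identity$trajectory, rep$baseline$trajectory)
  delta <- rep$summary[rep$summary$arm == "identity", -1] -
    rep$summary[rep$summary$arm == "baseline", -1]
  expect_true(all(abs(unlist(delta)) == 0))
  # the three time fractions always sum to one
  s <- rep$summary
  expect_equal(s$time_in_range + s$time_below_70 + s$time_above_180,
               rep(1, nrow(s)))
})

test_that("meal size and bolus dose shift glucose monotonically over their windows", {
  fx <- replay_fixture()
  rep <- replay_compare(fx$day, fx$fit, list(
    bigger_meal = list(modification("scale_meal", "meal2", 1.5)),
    smaller_meal = list(modification("scale_meal", "meal2", 0.5)),
    bigger_bolus = list(modification("scale_bolus", "bolus3", 1.5)),
    smaller_bolus = list(modification("scale_bolus", "bolus3", 0.5))))
  expect_length(rep$failed_arms, 0)
  g0 <- rep$baseline$trajectory$G
  tt <- rep$baseline$trajectory$time
  win <- tt > 780 & tt <= 1140  # lunch to dinner (next insulin event)
  expect_true(all(rep$arms$bigger_meal$trajectory$G[win] >= g0[win] - 1e-9))
  expect_true(all(rep$arms$smaller_meal$trajectory$G[win] <= g0[win] + 1e-9))
  expect_true(all(rep$arms$bigger_bolus$trajectory$G[win] <= g0[win] + 1e-9))
  expect_true(all(rep$arms$smaller_bolus$trajectory$G[win] >= g0[win] - 1e-9))
  # treatment differences have washed out by the end of the day
  last <- tt >= 1430
  expect_lt(max(abs(rep$arms$bigger_bolus$trajectory$G[last] - g0[last])), 5)
})

test_that("activity-duration arms stay ordered through the evening", {
  fx <- replay_fixture()
  durations <- c(21, 41, 61, 81)
  mods <- lapply(durations, function(d)
    list(modification("set_pa_duration", 1, d)))
  names(mods) <- paste0("dur", durations)
  rep <- replay_compare(fx$day, fx$fit, mods)
  tt <- rep$baseline$trajectory$time
  evening <- which(tt >= 1100)
  g_end <- vapply(rep$arms, function(a)
    mean(a$trajectory$G[evening]), numeric(1))
  # longer exercise leaves lower evening glucose (elevated sensitivity)
  expect_true(all(diff(g_end) < 0))
})

test_that("failed arms are reported without losing the others", {
  fx <- replay_fixture()
  rep <- suppressWarnings(replay_compare(fx$day, fx$fit, list(
    ok = list(modification("scale_meal", "meal2", 1.2)),
    bad = list(modification("set_pa_intensity", 5, 40)))))
  expect_equal(rep$failed_arms, "bad")
  expect_named(rep$arms, "ok")
})
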