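test_that("fit metrics equal their hand-computed values", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(110, 120), c(100, 110)), 10)
  expect_equal(rmsd(c(110, 90), c(100, 120)), sqrt((100 + 900) / 2))
  expect_equal(mard(c(1, 2), c(1, 2)), 0)
  expect_equal(mard(110, 100), 10)
  expect_equal(mard(c(90, 210), c(100, 200)), 7.5)
  expect_equal(rmsd(c(1, NA, 3), c(1, 2, 3)), 0)  # missing pairs dropped
  expect_error(rmsd(NA_real_, 1), "overlapping")
  expect_error(mard(c(1, 2), c(0, 2)), "positive")
  expect_error(rmsd(1:3, 1:2), "equal length")
})

test_that("noise-free personalization recovers the generating subject", {
  subj <- generate_subject(42, cv = 0.15, perturb = c("p1", "p3", "Gb"))
  sd1 <- generate_day(subj, day_template(), seed = 7, cgm_noise_sd = 0)
  fit <- personalize(sd1$day, pop_params())
  expect_true(fit$converged)
  expect_lt(abs(fit$params$p3 - subj$params$p3) / subj$params$p3, 0.01)
  expect_lt(abs(fit$params$Gb - subj$params$Gb) / subj$params$Gb, 0.01)
  expect_lt(abs(fit$params$p1 - subj$params$p1) / subj$params$p1, 0.01)
  expect_equal(fit$meal_params$f, sd1$truth$meal_params$f, tolerance = 1e-3)
  expect_equal(fit$meal_params$tau_m, sd1$truth$meal_params$tau_m,
               tolerance = 1e-3)
  expect_lt(fit$rmsd, 0.1)
  # accepted optimizer steps never increase the objective (beyond the
  # neutral-step tolerance of the bounded trust region)
  expect_true(all(diff(fit$rsstrace) <= 1e-3 * fit$rsstrace[-length(fit$rsstrace)] + 1e-12))
  # estimates respect their declared bounds
  expect_true(all(fit$bounds$value >= fit$bounds$lower - 1e-12))
  expect_true(all(fit$bounds$value <= fit$bounds$upper + 1e-12))
})

test_that("a day with no logged meals fits only the subject-level parameters", {
  subj <- generate_subject(8, cv = 0.1, perturb = c("p3", "Gb"))
  tmpl <- scenario(t_end = 1440,
                   boluses = list(insulin_bolus(300, 2),
                                  insulin_bolus(800, 1.5)),
                   basal = 0.8)
  sd1 <- generate_day(subj, tmpl, seed = 2, cgm_noise_sd = 0)
  expect_equal(nrow(sd1$day$meals), 0)
  fit <- personalize(sd1$day, pop_params())
  expect_null(fit$meal_params)
  expect_equal(names(fit$estimates), c("p1", "p3", "Gb"))
  expect_lt(abs(fit$params$p3 - subj$params$p3) / subj$params$p3, 0.02)
})

test_that("second-day evaluation freezes p1 and p3 and generalizes", {
  subj <- generate_subject(10, cv = 0.12, perturb = c("p1", "p3", "Gb"))
  sd1 <- generate_day(subj, day_template(), seed = 31, cgm_noise_sd = 5)
  fit1 <- personalize(sd1$day, pop_params())
  # same day again: frozen refit reproduces the metrics
  fit_same <- evaluate_second_day(sd1$day, fit1)
  expect_equal(fit_same$params$p1, fit1$params$p1)
  expect_equal(fit_same$params$p3, fit1$params$p3)
  expect_lt(fit_same$rmsd, fit1$rmsd + 1)
  # a distinct second day still fits well with day-1 subject parameters
  tmpl2 <- scenario(t_end = 1440,
                    meals = list(meal_event("08:00", 50, f = 0.85, tau_m = 40),
                                 meal_event("14:00", 45, f = 0.9, tau_m = 50),
                                 meal_event("19:30", 65, f = 0.8, tau_m = 35)),
                    boluses = list(insulin_bolus("08:00", 5),
                                   insulin_bolus("14:00", 4.5),
                                   insulin_bolus("19:30", 6.5)),
                    basal = 0.8)
  sd2 <- generate_day(subj, tmpl2, seed = 32, cgm_noise_sd = 5)
  fit2 <- evaluate_second_day(sd2$day, fit1)
  expect_equal(fit2$params$p1, fit1$params$p1)
  expect_lt(fit2$rmsd, 2 * max(fit1$rmsd, 5))
})

test_that("an unlogged meal shows up as a localized residual excursion", {
  subj <- generate_subject(12, cv = 0, perturb = character(0))
  sd1 <- generate_day(subj, day_template(), seed = 40, cgm_noise_sd = 5,
                      misreport = list(omit = 2))  # lunch missing from logbook
  fit <- personalize(sd1$day, pop_params())
  res <- fit$residuals
  lunch_win <- res$time >= 780 & res$time < 1020
  # residuals around the hidden meal dwarf those elsewhere, and excluding
  # the window recovers a good fit quality
  expect_gt(sqrt(mean(res$residual[lunch_win]^2)),
            2.5 * sqrt(mean(res$residual[!lunch_win]^2)))
  excl <- rmsd(res$model[!lunch_win], res$observed[!lunch_win])
  expect_gt(fit$rmsd, 1.4 * excl)
  expect_lt(excl, 15)
})

test_that("validation tuning recovers the exercise-response scale with fixed ratio", {
  p <- pop_params()
  sc <- scenario(t_end = 600,
                 meals = list(meal_event(30, 75, f = 0.9, tau_m = 105)),
                 boluses = list(insulin_bolus(30, 3)),
                 basal = 0.8,
                 activity = ac_trace_from_bouts(
                   data.frame(start = 150, duration = 60, intensity = 50)))
  # self-consistency: data simulated at params0 returns params0
  obs0 <- data.frame(time = seq(0, 600, 5),
                     glucose = glucose_at(simulate(sc, p), seq(0, 600, 5)))
  fit0 <- tune_validation_params(obs0, sc, p)
  expect_equal(fit0$params$b, p$b, tolerance = 1e-4)
  expect_equal(fit0$params$q1, p$q1, tolerance = 1e-4)
  # the fitted ratio always equals the input ratio
  expect_equal(fit0$params$q1 / fit0$params$q2, p$q1 / p$q2, tolerance = 1e-12)
  expect_error(tune_validation_params(obs0, scenario(t_end = 100), p),
               "activity")
})

test_that("profile likelihood brackets the truth and touches the fit optimum", {
  subj <- generate_subject(15, cv = 0.1, perturb = c("p3", "Gb"))
  tmpl <- day_template(with_activity = FALSE, t_end = 720)
  sd1 <- generate_day(subj, tmpl, seed = 50, cgm_noise_sd = 3)
  fit <- personalize(sd1$day, pop_params(),
                     config = list(free = c("p3", "Gb")))
  grid <- fit$params$p3 * c(0.7, 0.85, 1, 1.15, 1.3)
  prof <- profile_likelihood_ci(fit, "p3", grid)
  expect_equal(min(prof$profile), prof$rss_min, tolerance = 0.05 * prof$rss_min)
  expect_gte(min(prof$profile), fit$rss - 0.01 * fit$rss)
  # profile rises away from the optimum and the CI brackets the truth
  expect_gt(prof$profile[1], prof$threshold)
  expect_gt(prof$profile[5], prof$threshold)
  expect_true(all(prof$identifiable))
  expect_lte(prof$ci[["lower"]], subj$params$p3)
  expect_gte(prof$ci[["upper"]], subj$params$p3)
  expect_error(profile_likelihood_ci(fit, "p3", c(1, 2)), "3 grid points")
  expect_error(profile_likelihood_ci(fit, "q6", grid), "not a free parameter")
})
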