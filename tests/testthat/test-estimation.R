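test_that("exponential sub-case reproduces the closed-form MLE", {
  set.seed(21)
  t <- rexp(400, rate = 0.02)
  fit <- fit_weibull_censored(t, rep(TRUE, 400), fix_p = 1)
  expect_equal(fit$L, 400 / sum(t), tolerance = 1e-6)
  expect_identical(fit$p, 1)
  # fixed-p closed form at other shapes too
  fit2 <- fit_weibull_censored(t, rep(TRUE, 400), fix_p = 2)
  expect_equal(fit2$L, (400 / sum(t^2))^(1 / 2), tolerance = 1e-6)
})

test_that("parameters are recovered from simulated data", {
  set.seed(22)
  t <- rweibull(5000, shape = 1.5, scale = 1 / 0.01)
  fit <- fit_weibull_censored(t, rep(TRUE, 5000))
  expect_equal(fit$L, 0.01, tolerance = 0.05)
  expect_equal(fit$p, 1.5, tolerance = 0.05)
  # ~50% censoring at a fixed time
  t2 <- rweibull(10000, shape = 2, scale = 1 / 0.005)
  cens_at <- median(t2)
  ev <- t2 <= cens_at
  t2c <- pmin(t2, cens_at)
  fit2 <- fit_weibull_censored(t2c, ev)
  expect_equal(fit2$L, 0.005, tolerance = 0.05)
  expect_equal(fit2$p, 2, tolerance = 0.05)
})

test_that("mean relative bias at n = 5000 stays below 2%", {
  set.seed(23)
  biasL <- biasP <- numeric(20)
  for (r in 1:20) {
    t <- rweibull(5000, shape = 1.3, scale = 1 / 0.02)
    fit <- fit_weibull_censored(t, rep(TRUE, 5000))
    biasL[r] <- (fit$L - 0.02) / 0.02
    biasP[r] <- (fit$p - 1.3) / 1.3
  }
  expect_lt(abs(mean(biasL)), 0.02)
  expect_lt(abs(mean(biasP)), 0.02)
})

test_that("optimiser matches the survreg oracle under censoring", {
  skip_if_not_installed("survival")
  set.seed(24)
  t <- rweibull(800, shape = 0.8, scale = 1 / 0.03)
  ev <- t <= 60
  tc <- pmin(t, 60)
  fit <- fit_weibull_censored(tc, ev)
  sr <- survival::survreg(survival::Surv(tc, ev) ~ 1, dist = "weibull")
  expect_equal(fit$L, exp(-unname(coef(sr))), tolerance = 1e-4)
  expect_equal(fit$p, 1 / sr$scale, tolerance = 1e-4)
})

test_that("censored records at identical times contribute deterministically", {
  set.seed(25)
  t <- rweibull(300, 1.4, 1 / 0.01)
  ev <- t <= 80
  tc <- pmin(t, 80)
  f1 <- fit_weibull_censored(tc, ev)
  # removing and re-adding the censored rows in a different order
  o <- c(which(ev), rev(which(!ev)))
  f2 <- fit_weibull_censored(tc[o], ev[o])
  expect_identical(c(f1$L, f1$p), c(f2$L, f2$p))
})

test_that("bootstrap is deterministic, bounded and degenerate-safe", {
  set.seed(26)
  t <- rweibull(120, 1.2, 1 / 0.02)
  ev <- rep(TRUE, 120)
  b1 <- bootstrap_weibull(t, ev, B = 120, seed = 99)
  b2 <- bootstrap_weibull(t, ev, B = 120, seed = 99)
  expect_identical(b1, b2)
  expect_true(abs(b1$corr_Lp) <= 1)
  pt <- fit_weibull_censored(t, ev)
  expect_identical(c(b1$L, b1$p), c(pt$L, pt$p))  # point estimates unchanged
  # degenerate data: every resample is the same dataset
  td <- rep(5, 50)
  bd <- bootstrap_weibull(td, rep(TRUE, 50), B = 100, seed = 1, fix_p = 1)
  expect_identical(bd$se_L, 0)
})

test_that("bootstrap SE approximates the analytic exponential SE", {
  set.seed(27)
  t <- rexp(2000, rate = 0.05)
  b <- bootstrap_weibull(t, rep(TRUE, 2000), B = 200, seed = 5, fix_p = 1)
  expect_equal(b$se_L, b$L / sqrt(2000), tolerance = 0.2)
})

test_that("constant hazards match observed occurrence rates", {
  expect_identical(estimate_constant_hazard(0, 500)$hourly_prob, 0)
  est <- estimate_constant_hazard(10, 10000)
  expect_equal(est$hourly_prob, 1 - exp(-0.001))
  # round trip: simulating with this hourly probability reproduces the count
  set.seed(28)
  events <- rbinom(50, size = 10000, prob = est$hourly_prob)
  expect_lt(abs(mean(events) - 10), 3 * sd(events) / sqrt(50))
  expect_error(estimate_constant_hazard(-1, 10), "n_events")
})

test_that("zero-dwell fractions are counted and recovered", {
  expect_equal(estimate_zero_dwell_fraction(c(0, 0, 5, 12)), 0.5)
  expect_equal(estimate_zero_dwell_fraction(c(0, 0)), 1)
  set.seed(29)
  d <- ifelse(runif(10000) < 0.3, 0, rweibull(10000, 1.2, 10))
  expect_equal(estimate_zero_dwell_fraction(d), 0.3, tolerance = 0.02 / 0.3)
})

test_that("mean daily doses mirror the dose-record table", {
  one <- data.frame(patient_id = "a", arm = "CS", phase = "before_weaning",
                    drug = "morphine", total_mg_per_day = 70)
  m1 <- mean_daily_doses(one)
  expect_equal(m1$mean_mg_per_day, 70)
  expect_equal(m1$se, 0)
  two <- data.frame(patient_id = c("a", "b"), arm = "CS",
                    phase = "before_weaning", drug = "morphine",
                    total_mg_per_day = c(60, 80))
  m2 <- mean_daily_doses(two)
  expect_equal(m2$mean_mg_per_day, 70)
  expect_equal(m2$se, 10)
  # generated cohort recovers the published summary within 2 SE
  set.seed(30)
  tr <- generate_trial(trial_design(), seed = 31)
  md <- mean_daily_doses(tr$dose_records)
  row <- md[md$arm == "CS" & md$phase == "before_weaning" &
              md$drug == "morphine", ]
  expect_lt(abs(row$mean_mg_per_day - 71.7), 2 * 17.8)
})

test_that("the full estimation pipeline returns a complete parameter set", {
  tr <- generate_trial(trial_design(n_CS = 400, n_RS = 400), seed = 32)
  est <- estimate_trial_params(tr$phase_records)
  expect_s3_class(est, "model_params")
  expect_true(all(c("CS", "RS") %in% names(est$s1_progress)))
  expect_gt(est$s1_switch$L, 0)
  expect_true(est$s3_death$hourly_prob >= 0 && est$s3_death$hourly_prob < 0.01)
})
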