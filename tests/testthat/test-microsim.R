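test_that("forced paths traverse the state machine as designed", {
  specs <- constant_specs(q1 = 1, q3 = 1, q5 = 1)
  set.seed(61)
  h <- simulate_patient("CS", specs)
  expect_identical(h$terminal, "discharged")
  on_dwell <- h$segments[h$segments$exit > h$segments$entry, ]
  expect_identical(on_dwell$state, c(1L, 3L, 5L))
  expect_identical(max(h$segments$exit), 3L)
  expect_identical(h$weaning_start_hour, 1L)
  # certain death in the first hour (sole exit, so no renormalisation)
  specs_d <- constant_specs(q1 = 0, q3 = 1, q5 = 1, death1 = 1)
  set.seed(62)
  hd <- simulate_patient("RS", specs_d)
  expect_identical(hd$terminal, "death")
  expect_identical(max(hd$segments$exit), 1L)
})

test_that("geometric dwell means match constant-hazard theory", {
  specs <- constant_specs(q1 = 0.1, q3 = 0.125, q5 = 0.2)
  res <- run_cohort(50000, specs, seed = 63)
  expected_h <- 1 / 0.1 + 1 / 0.125 + 1 / 0.2
  cs <- res$patients[res$patients$arm == "CS", ]
  mc_se <- sd(cs$hours_icu) / sqrt(nrow(cs))
  expect_lt(abs(mean(cs$hours_icu) - expected_h), 3 * mc_se)
  # per-phase mean for state 1 alone
  expect_lt(abs(mean(cs$hours_mv) - (1 / 0.1 + 1 / 0.125)),
            3 * sd(cs$hours_mv) / sqrt(nrow(cs)))
})

test_that("identical arms under common random numbers differ by exactly zero", {
  specs <- constant_specs(q1 = 0.05, q3 = 0.08, q5 = 0.1, death1 = 0.002)
  # arm-symmetric sedation rates, so the cost difference can vanish too
  costs <- cost_params(sed_before = c(CS = 2, RS = 2),
                       sed_during = c(CS = 1, RS = 1))
  res <- run_cohort(1500, specs, costs, seed = 64, common_rng = TRUE)
  expect_identical(unname(res$diff), c(0, 0, 0))
})

test_that("cohort runs are reproducible and respect hard invariants", {
  p <- demo_params()
  r1 <- run_cohort(800, p, seed = 65)
  r2 <- run_cohort(800, p, seed = 65)
  expect_identical(r1, r2)
  pats <- r1$patients
  expect_true(all(pats$hours_mv <= pats$hours_icu))
  expect_true(all(pats$hours_icu <= 672))
  expect_true(all(pats$terminal %in%
                    c("discharged", "death", "horizon_censored")))
  # switching only happens to remifentanil patients during maintenance
  sw <- pats[!is.na(pats$switched_at), ]
  expect_true(all(sw$arm == "RS"))
  expect_gt(nrow(sw), 0)
})

test_that("histories are contiguous and ordered through states 1 to 7", {
  res <- run_cohort(300, demo_params(), seed = 66, keep_histories = TRUE)
  seg <- res$segments
  for (pid in unique(seg$id)[1:50]) {
    s <- seg[seg$id == pid, ]
    expect_identical(s$entry[1], 0L)
    if (nrow(s) > 1) {
      expect_identical(s$entry[-1], s$exit[-nrow(s)])
      expect_true(all(diff(s$state) >= 0))
    }
  }
})

test_that("faster progression in one arm yields positive LOS differences", {
  wb <- weibull_params
  p <- tiny_params()
  p$s1_progress$RS <- wb(0.04, 1)   # RS leaves maintenance twice as fast
  signs <- sapply(1:5, function(s) {
    run_cohort(2000, p, seed = 70 + s)$diff[["los_icu_days"]]
  })
  expect_true(all(signs > 0))
})

test_that("the on-label subgroup filter uses the 72-hour boundary inclusively", {
  res <- run_cohort(400, demo_params(), seed = 67)
  ws <- res$patients$weaning_start_hour
  sub <- onlabel_subgroup(res)
  expect_identical(sum(sub$arms$n),
                   sum(!is.na(ws) & ws <= 72))
  # manual boundary check on a doctored cohort
  res2 <- res
  res2$patients$weaning_start_hour <-
    rep(c(72L, 73L), length.out = nrow(res2$patients))
  sub2 <- onlabel_subgroup(res2)
  expect_identical(sum(sub2$arms$n), sum(res2$patients$weaning_start_hour == 72))
  # empty subgroup reports absence instead of failing
  res3 <- res
  res3$patients$weaning_start_hour <- NA_integer_
  expect_message(out <- onlabel_subgroup(res3), "empty")
  expect_null(out)
})

test_that("single forced trajectory prices out exactly", {
  specs <- constant_specs(q1 = 1, q3 = 1, q5 = 1)
  costs <- default_cost_params()
  res <- run_cohort(1, specs, costs, seed = 68)
  expect_equal(res$arms$mean_los_icu_days, rep(3 / 24, 2))
  sed1 <- costs$sed_before[["CS"]]
  sed3 <- costs$sed_during[["CS"]]
  expect_equal(res$arms$mean_cost_eur[res$arms$arm == "CS"],
               (2106 / 24 + sed1) + (2106 / 24 + sed3) + 1645 / 24)
})
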