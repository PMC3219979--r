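test_that("hourly sedation cost is the price-weighted daily dose over 24", {
  expect_identical(sedation_cost_per_hour(c(morphine = 0, propofol = 0)), 0)
  expect_equal(sedation_cost_per_hour(c(propofol = 240)), 240 * 0.02 / 24)
  expect_error(sedation_cost_per_hour(c(ketamine = 10)), "unknown drug")
  expect_error(sedation_cost_per_hour(c(morphine = -1)), "nonnegative")
})

test_that("worked single-patient cost arithmetic is exact", {
  costs <- default_cost_params()
  # conventional arm: 120 h ventilated maintenance, 48 h post-extubation
  hist_cs <- list(arm_initial = "CS", switched_at = NA,
                  segments = data.frame(state = c(1L, 5L),
                                        entry = c(0, 120),
                                        exit = c(120, 168)))
  expect_equal(accumulate_costs(hist_cs, costs),
               120 * (2106 / 24 + 1.30) + 48 * (1645 / 24))
  # remifentanil patient switching at hour 24, censored at 48 h
  hist_rs <- list(arm_initial = "RS", switched_at = 24,
                  segments = data.frame(state = c(1L, 1L),
                                        entry = c(0, 24), exit = c(24, 48)))
  expect_equal(accumulate_costs(hist_rs, costs),
               24 * (2106 / 24 + 7.47) + 24 * (2106 / 24 + 1.30))
  # an unsplit segment straddling the switch gives the same total
  hist_rs2 <- list(arm_initial = "RS", switched_at = 24,
                   segments = data.frame(state = 1L, entry = 0, exit = 48))
  expect_equal(accumulate_costs(hist_rs2, costs),
               accumulate_costs(hist_rs, costs))
  # empty history costs nothing
  expect_identical(accumulate_costs(list(arm_initial = "CS",
                                         switched_at = NA,
                                         segments = NULL), costs), 0)
})

test_that("cost is additive over any partition and monotone in stay", {
  costs <- default_cost_params()
  set.seed(41)
  base <- list(arm_initial = "CS", switched_at = NA,
               segments = data.frame(state = c(1L, 3L, 5L),
                                     entry = c(0, 90, 130),
                                     exit = c(90, 130, 200)))
  total <- accumulate_costs(base, costs)
  # split the first segment at an arbitrary interior point
  for (cut in c(1, 45.5, 89)) {
    split <- base
    split$segments <- rbind(
      data.frame(state = 1L, entry = 0, exit = cut),
      data.frame(state = 1L, entry = cut, exit = 90),
      base$segments[-1, ])
    expect_identical(accumulate_costs(split, costs), total)
  }
  longer <- base
  longer$segments$exit[3] <- 201
  expect_gt(accumulate_costs(longer, costs), total)
})

test_that("with sedation zeroed the total is the pure bed cost", {
  costs <- cost_params(sed_before = c(CS = 0, RS = 0),
                       sed_during = c(CS = 0, RS = 0))
  hist <- list(arm_initial = "RS", switched_at = NA,
               segments = data.frame(state = c(1L, 3L, 5L, 6L),
                                     entry = c(0, 50, 80, 100),
                                     exit = c(50, 80, 100, 112)))
  expect_equal(accumulate_costs(hist, costs),
               80 * 2106 / 24 + 32 * 1645 / 24)
})

test_that("segment validation rejects gaps and overlaps", {
  costs <- default_cost_params()
  gap <- list(arm_initial = "CS", switched_at = NA,
              segments = data.frame(state = c(1L, 3L),
                                    entry = c(0, 60), exit = c(50, 80)))
  expect_error(accumulate_costs(gap, costs), "contiguous")
  late <- list(arm_initial = "CS", switched_at = NA,
               segments = data.frame(state = 1L, entry = 5, exit = 10))
  expect_error(accumulate_costs(late, costs), "hour 0")
})

test_that("vectorised cohort costing agrees with the per-patient rule", {
  res <- run_cohort(150, demo_params(), seed = 51, keep_histories = TRUE)
  costs <- default_cost_params()
  set.seed(52)
  for (pid in sample(res$patients$id, 25)) {
    p <- res$patients[res$patients$id == pid, ]
    seg <- res$segments[res$segments$id == pid, c("state", "entry", "exit")]
    hist <- list(arm_initial = p$arm, switched_at = p$switched_at,
                 segments = seg)
    expect_equal(accumulate_costs(hist, costs), unname(p$cost_eur))
  }
})
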