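test_that("survivor function matches its closed form", {
  w <- weibull_params(L = 0.01, p = 1.5)
  expect_identical(weibull_survival(0, w), 1)
  expect_equal(weibull_survival(1 / 0.01, w), exp(-1))
  expect_equal(weibull_survival(100, w), exp(-1))
  expect_equal(weibull_survival(50, w), exp(-0.5^1.5))
  w2 <- weibull_params(L = 0.2, p = 0.7)
  expect_equal(weibull_survival(1 / 0.2, w2), exp(-1))
  expect_error(weibull_survival(-1, w), "nonnegative")
  expect_error(weibull_params(L = -1, p = 1), "positive")
  expect_error(weibull_params(L = 1, p = 1, corr_Lp = 1.5), "corr")
})

test_that("hourly transition probability is 1 - S(t)/S(t-1)", {
  w <- weibull_params(L = 0.02, p = 2)
  expect_equal(hourly_transition_prob(1, w), 1 - exp(-(0.02)^2))
  expect_gt(hourly_transition_prob(10, w), hourly_transition_prob(2, w))
  # exponential special case: constant and exact at machine precision
  we <- weibull_params(L = 0.05, p = 1)
  tp <- hourly_transition_prob(c(1, 7, 300, 672), we)
  expect_identical(tp, rep(-expm1(-0.05), 4))
  expect_error(hourly_transition_prob(0, w), ">= 1")
})

test_that("survival decreases, tp stays in [0,1), and the product identity holds", {
  set.seed(11)
  for (i in 1:20) {
    w <- weibull_params(L = runif(1, 0.001, 0.1), p = runif(1, 0.4, 3))
    s <- weibull_survival(0:672, w)
    expect_true(all(diff(s) < 0 | s[-1] == 0))  # strict until underflow
    tp <- hourly_transition_prob(1:672, w)
    expect_true(all(tp >= 0 & tp < 1))
    # prod_{t<=T}(1 - tp(t)) telescopes back to S(T)
    expect_equal(prod(1 - tp), weibull_survival(672, w), tolerance = 1e-10)
    if (w$p > 1) expect_true(all(diff(tp) >= 0))
  }
})

test_that("transition tables reproduce their defining hazards", {
  spec <- phase_spec(5L, "CS", list(progress = exit_constant(6L, 0.001)))
  tab <- build_transition_table(spec, horizon = 100L)
  expect_equal(unname(tab[, "progress"]), rep(0.001, 100))

  w <- weibull_params(0.01, 1.6)
  spec2 <- phase_spec(3L, "RS", list(progress = exit_weibull(4L, w)))
  tab2 <- build_transition_table(spec2, horizon = 50L)
  expect_equal(unname(tab2[, "progress"]), hourly_transition_prob(1:50, w))

  # competing causes are ordered death -> switch -> progress
  spec3 <- phase_spec(1L, "RS", list(
    progress = exit_weibull(2L, w), switch = exit_weibull(1L, w),
    death = exit_weibull(8L, w)))
  expect_identical(colnames(build_transition_table(spec3, 5L)),
                   c("death", "switch", "progress"))
})

test_that("rows whose naive sum exceeds one are renormalised proportionally", {
  w <- weibull_params(0.5, 3)  # hourly probabilities approach 1 quickly
  spec <- phase_spec(1L, "CS", list(
    progress = exit_weibull(2L, w), death = exit_constant(8L, 0.8)))
  expect_warning(tab <- build_transition_table(spec, horizon = 20L),
                 "renormalising")
  expect_true(all(rowSums(tab) <= 1 + 1e-12))
  # renormalisation preserves the relative share of each cause
  naive_p <- hourly_transition_prob(1:20, w)
  bad <- naive_p + 0.8 > 1
  expect_equal(tab[bad, "death"] / tab[bad, "progress"],
               0.8 / naive_p[bad])
})

test_that("zero-dwell mixtures carry their pass-through fraction", {
  w <- weibull_params(0.1, 1.2)
  spec <- phase_spec(2L, "CS",
                     list(progress = exit_zero_dwell(3L, 0.4, w)))
  tab <- build_transition_table(spec, 30L)
  expect_equal(attr(tab, "zero_fraction"), 0.4)
  expect_equal(unname(tab[, "progress"]), hourly_transition_prob(1:30, w))
  expect_error(exit_zero_dwell(3L, 0.4), "Weibull component")
  expect_silent(exit_zero_dwell(3L, 1))
})

test_that("phase specifications enforce the state machine structure", {
  w <- weibull_params(0.01, 1)
  expect_error(phase_spec(2L, "CS", list(
    progress = exit_weibull(3L, w), switch = exit_weibull(2L, w))),
    "switch")
  expect_error(phase_spec(1L, "CS", list(death = exit_weibull(8L, w))),
               "progression")
  expect_error(phase_spec(7L, "CS", list(progress = exit_weibull(8L, w))),
               "1-6")
  hs <- health_states()
  expect_identical(nrow(hs), 8L)
  expect_identical(hs$id[hs$absorbing], c(7L, 8L))
  expect_identical(hs$id[hs$on_mv], 1:4)
})
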