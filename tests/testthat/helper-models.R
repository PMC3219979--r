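# Shared builders for engine-level tests.

# a minimal but complete parameter set with simple values
tiny_params <- function(death_L = 1e-9, switch_L = 1e-9,
                        zero2 = 1, zero4 = 1, zero6 = 1) {
  wb <- weibull_params
  dwell2 <- if (zero2 < 1) wb(0.1, 1) else NULL
  dwell4 <- if (zero4 < 1) wb(0.1, 1) else NULL
  dwell6 <- if (zero6 < 1) wb(0.1, 1) else NULL
  model_params(
    s1_progress = list(CS = wb(0.02, 1), RS = wb(0.02, 1)),
    s1_death = wb(death_L, 1),
    s1_switch = wb(switch_L, 1),
    s2 = list(zero_fraction = c(CS = zero2, RS = zero2),
              zero_fraction_se = c(CS = 0, RS = 0),
              dwell = list(CS = dwell2, RS = dwell2)),
    s3_progress = list(CS = wb(0.03, 1), RS = wb(0.03, 1)),
    s3_death = list(hourly_prob = 0, se = 0),
    s4 = list(zero_fraction = c(CS = zero4, RS = zero4),
              zero_fraction_se = c(CS = 0, RS = 0),
              dwell = list(CS = dwell4, RS = dwell4)),
    s5_progress = wb(0.04, 1),
    s5_death = list(hourly_prob = 0, se = 0),
    s6 = list(zero_fraction = zero6, zero_fraction_se = 0, dwell = dwell6))
}

# hand-built specs: constant progression hazards q1, q3, q5; states
# 2/4/6 passed through instantly; optional constant death in state 1
constant_specs <- function(q1, q3, q5, death1 = 0) {
  one_arm <- function(arm) {
    e1 <- list(progress = exit_constant(2L, q1))
    if (death1 > 0) e1$death <- exit_constant(8L, death1)
    list(
      phase_spec(1L, arm, e1),
      phase_spec(2L, arm, list(progress = exit_zero_dwell(3L, 1))),
      phase_spec(3L, arm, list(progress = exit_constant(4L, q3))),
      phase_spec(4L, arm, list(progress = exit_zero_dwell(5L, 1))),
      phase_spec(5L, arm, list(progress = exit_constant(6L, q5))),
      phase_spec(6L, arm, list(progress = exit_zero_dwell(7L, 1))))
  }
  list(CS = one_arm("CS"), RS = one_arm("RS"))
}

# strip all uncertainty from a parameter set (point estimates only)
zero_se_params <- function(p) {
  z <- function(w) if (is.null(w)) NULL else weibull_params(w$L, w$p, 0, 0, 0)
  model_params(
    s1_progress = lapply(p$s1_progress, z),
    s1_death = z(p$s1_death), s1_switch = z(p$s1_switch),
    s2 = list(zero_fraction = p$s2$zero_fraction,
              zero_fraction_se = c(CS = 0, RS = 0),
              dwell = lapply(p$s2$dwell, z)),
    s3_progress = lapply(p$s3_progress, z),
    s3_death = list(hourly_prob = p$s3_death$hourly_prob, se = 0),
    s4 = list(zero_fraction = p$s4$zero_fraction,
              zero_fraction_se = c(CS = 0, RS = 0),
              dwell = lapply(p$s4$dwell, z)),
    s5_progress = z(p$s5_progress),
    s5_death = list(hourly_prob = p$s5_death$hourly_prob, se = 0),
    s6 = list(zero_fraction = p$s6$zero_fraction, zero_fraction_se = 0,
              dwell = z(p$s6$dwell)))
}

zero_se_costs <- function(costs = default_cost_params()) {
  cost_params(sed_before = costs$sed_before, sed_during = costs$sed_during,
              sed_before_se = c(CS = 0, RS = 0),
              sed_during_se = c(CS = 0, RS = 0),
              icu_day_mv = costs$icu_day_mv, icu_day_mv_se = 0,
              icu_day_nomv = costs$icu_day_nomv, icu_day_nomv_se = 0)
}

# brute-force grid maximiser of the censored Weibull log-likelihood,
# iteratively refined to step 1e-4 in (log L, log p) space; independent
# of the package optimiser
grid_weibull_loglik <- function(time, event) {
  ll <- function(logL, logp) {
    L <- exp(logL); p <- exp(logp)
    te <- time[event]
    sum(log(p) + p * (logL + log(te)) - log(te)) - sum((L * time)^p)
  }
  cl <- log(sum(event) / sum(time)); cp <- 0
  width <- 2
  repeat {
    step <- width / 40
    gl <- seq(cl - width, cl + width, by = step)
    gp <- seq(cp - width, cp + width, by = step)
    vals <- outer(gl, gp, Vectorize(ll))
    i <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    cl <- gl[i[1]]; cp <- gp[i[2]]
    if (step <= 1e-4) break
    width <- 2.5 * step
  }
  list(logL = cl, logp = cp, loglik = ll(cl, cp))
}
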