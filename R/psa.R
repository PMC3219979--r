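# Probabilistic sensitivity analysis: every input parameter is redrawn
# from its uncertainty distribution, the cohort model is rerun, and the
# distribution of the arm differences is summarised with percentile
# intervals and probabilities of saving.

.Z99 <- qnorm(0.99)

# draw a correlated (L, p) pair. Marginals are normal unless a normal
# draw would put more than 1% mass below zero for either parameter, in
# which case moment-matched lognormals are used (with the correlation
# applied on the log scale). p is drawn conditionally on the drawn L
# using the bivariate-normal conditional mean and variance.
.draw_weibull_pair <- function(w, max_tries = 100L) {
  se_L <- if (is.na(w$se_L)) 0 else w$se_L
  se_p <- if (is.na(w$se_p)) 0 else w$se_p
  rho <- if (is.na(w$corr_Lp)) 0 else w$corr_Lp
  if (se_L == 0 && se_p == 0) return(weibull_params(w$L, w$p))
  lognormal <- (se_L > 0 && w$L / se_L < .Z99) ||
    (se_p > 0 && w$p / se_p < .Z99)
  if (lognormal) {
    m2s <- function(m, s) {
      if (s == 0) return(c(log(m), 0))
      v <- log1p((s / m)^2); c(log(m) - v / 2, sqrt(v))
    }
    mL <- m2s(w$L, se_L); mp <- m2s(w$p, se_p)
    zL <- rnorm(1)
    zp <- rho * zL + sqrt(1 - rho^2) * rnorm(1)
    return(weibull_params(exp(mL[1] + mL[2] * zL), exp(mp[1] + mp[2] * zp)))
  }
  for (i in seq_len(max_tries)) {
    Ld <- rnorm(1, w$L, se_L)
    pd <- if (se_L > 0)
      rnorm(1, w$p + rho * se_p / se_L * (Ld - w$L), se_p * sqrt(1 - rho^2))
    else rnorm(1, w$p, se_p)
    if (Ld > 0 && pd > 0) return(weibull_params(Ld, pd))
  }
  stop("could not draw a positive (L, p) pair in ", max_tries, " attempts",
       call. = FALSE)
}

.draw_trunc <- function(mean, se, lower = 0, upper = Inf,
                        max_tries = 100L) {
  if (is.na(se) || se == 0) return(mean)
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, se)
    if (x >= lower && x <= upper) return(x)
  }
  stop("could not draw a parameter inside its domain in ", max_tries,
       " attempts", call. = FALSE)
}

#' Draw one full parameter set from its uncertainty distributions
#'
#' Weibull pairs are drawn jointly (L first, then p conditional on the
#' drawn L, using the bootstrap correlation); constant hourly death
#' probabilities and zero-dwell fractions as normals truncated to their
#' domains; the four sedation hourly costs and two ICU day costs as
#' independent normals truncated at zero. Parameters with zero (or
#' missing) standard error stay at their point estimate.
#'
#' @param params a [model_params()] object carrying standard errors.
#' @param costs a [cost_params()] object.
#' @return `list(params = , costs = )` with every parameter redrawn.
#' @export
draw_parameter_set <- function(params, costs) {
  p <- params
  dw <- function(lst) if (is.null(lst)) NULL else .draw_weibull_pair(lst)
  zf <- function(z, se) {
    out <- z
    for (i in seq_along(z))
      out[i] <- .draw_trunc(z[i], if (length(se) >= i) se[i] else 0, 0, 1)
    out
  }
  newp <- model_params(
    s1_progress = lapply(p$s1_progress, dw),
    s1_death = dw(p$s1_death),
    s1_switch = dw(p$s1_switch),
    s2 = list(zero_fraction = zf(p$s2$zero_fraction, p$s2$zero_fraction_se),
              zero_fraction_se = p$s2$zero_fraction_se,
              dwell = lapply(p$s2$dwell, dw)),
    s3_progress = lapply(p$s3_progress, dw),
    s3_death = list(hourly_prob = .draw_trunc(p$s3_death$hourly_prob,
                                              p$s3_death$se %||% 0, 0, 1),
                    se = p$s3_death$se),
    s4 = list(zero_fraction = zf(p$s4$zero_fraction, p$s4$zero_fraction_se),
              zero_fraction_se = p$s4$zero_fraction_se,
              dwell = lapply(p$s4$dwell, dw)),
    s5_progress = dw(p$s5_progress),
    s5_death = list(hourly_prob = .draw_trunc(p$s5_death$hourly_prob,
                                              p$s5_death$se %||% 0, 0, 1),
                    se = p$s5_death$se),
    s6 = list(zero_fraction = .draw_trunc(p$s6$zero_fraction,
                                          p$s6$zero_fraction_se %||% 0, 0, 1),
              zero_fraction_se = p$s6$zero_fraction_se,
              dwell = dw(p$s6$dwell)))
  newc <- cost_params(
    sed_before = c(CS = .draw_trunc(costs$sed_before[["CS"]],
                                    costs$sed_before_se[["CS"]]),
                   RS = .draw_trunc(costs$sed_before[["RS"]],
                                    costs$sed_before_se[["RS"]])),
    sed_during = c(CS = .draw_trunc(costs$sed_during[["CS"]],
                                    costs$sed_during_se[["CS"]]),
                   RS = .draw_trunc(costs$sed_during[["RS"]],
                                    costs$sed_during_se[["RS"]])),
    sed_before_se = costs$sed_before_se, sed_during_se = costs$sed_during_se,
    icu_day_mv = .draw_trunc(costs$icu_day_mv, costs$icu_day_mv_se),
    icu_day_mv_se = costs$icu_day_mv_se,
    icu_day_nomv = .draw_trunc(costs$icu_day_nomv, costs$icu_day_nomv_se),
    icu_day_nomv_se = costs$icu_day_nomv_se)
  list(params = newp, costs = newc)
}

# percentile interval endpoints as exact order statistics
.pctl_ci <- function(x, level = 0.95) {
  s <- sort(x)
  n <- length(s)
  a <- (1 - level) / 2
  lo <- s[max(1L, ceiling(a * n))]
  hi <- s[min(n, ceiling((1 - a) * n))]
  c(lower = lo, upper = hi)
}

#' Run the probabilistic sensitivity analysis
#'
#' Repeats `n_reps` times: draw a complete parameter set from its
#' uncertainty distributions, rerun the cohort model, and record the
#' per-arm mean outcomes and their conventional-minus-remifentanil
#' differences. The inner cohorts of every replicate reuse one fixed
#' random-number stream (common random numbers across replicates), so the
#' spread of the replicates reflects parameter uncertainty rather than
#' resampled patient-level noise; with all standard errors zero the
#' replicates are identical. A replicate whose parameter draw fails is
#' redrawn; more than 5% failures aborts.
#'
#' @param params a [model_params()] with standard errors.
#' @param costs a [cost_params()].
#' @param n_reps outer replicates (default 1500).
#' @param n_per_arm inner cohort size per arm per replicate (default
#'   2000; raise it for smoother replicate-level outcomes).
#' @param seed integer seed governing all randomness.
#' @param horizon follow-up hours.
#' @param subgroup if TRUE, the on-label subgroup (weaning within 72 h)
#'   differences are recorded per replicate as well.
#' @param common_rng forwarded to [run_cohort()]; TRUE by default (see
#'   above).
#' @return object of class `psa_result`: list with `n_reps`, `replicates`
#'   (one row per replicate: per-arm means and differences), and
#'   `summary` (per outcome: point mean over replicates, exact
#'   order-statistic 95% percentile interval, and `p_diff_positive`, the
#'   fraction of replicates in which conventional minus remifentanil is
#'   positive, i.e. the probability that the remifentanil regimen saves).
#' @export
run_psa <- function(params, costs = default_cost_params(), n_reps = 1500L,
                    n_per_arm = 2000L, seed = NULL, horizon = 672L,
                    subgroup = FALSE, common_rng = TRUE) {
  .assert(n_reps >= 2, "n_reps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  inner_seed <- sample.int(.Machine$integer.max, 1L)
  reps <- vector("list", n_reps)
  failures <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      draw <- tryCatch(draw_parameter_set(params, costs),
                       error = function(e) NULL)
      if (!is.null(draw)) break
      failures <- failures + 1L
      .assert(failures <= 0.05 * n_reps,
              "more than 5% of PSA parameter draws failed")
    }
    outer_state <- .Random.seed
    res <- run_cohort(n_per_arm, draw$params, draw$costs, seed = inner_seed,
                      horizon = horizon, common_rng = common_rng)
    row <- data.frame(
      rep = b,
      los_icu_RS = res$arms$mean_los_icu_days[res$arms$arm == "RS"],
      los_icu_CS = res$arms$mean_los_icu_days[res$arms$arm == "CS"],
      los_mv_RS = res$arms$mean_los_mv_days[res$arms$arm == "RS"],
      los_mv_CS = res$arms$mean_los_mv_days[res$arms$arm == "CS"],
      cost_RS = res$arms$mean_cost_eur[res$arms$arm == "RS"],
      cost_CS = res$arms$mean_cost_eur[res$arms$arm == "CS"],
      diff_los_icu = res$diff[["los_icu_days"]],
      diff_los_mv = res$diff[["los_mv_days"]],
      diff_cost = res$diff[["cost_eur"]])
    if (subgroup) {
      sg <- onlabel_subgroup(res)
      row$sub_diff_los_icu <- if (is.null(sg)) NA else sg$diff[["los_icu_days"]]
      row$sub_diff_los_mv <- if (is.null(sg)) NA else sg$diff[["los_mv_days"]]
      row$sub_diff_cost <- if (is.null(sg)) NA else sg$diff[["cost_eur"]]
    }
    reps[[b]] <- row
    assign(".Random.seed", outer_state, envir = globalenv())
  }
  replicates <- do.call(rbind, reps)
  outcomes <- grep("^(sub_)?diff_", names(replicates), value = TRUE)
  summ <- do.call(rbind, lapply(outcomes, function(oc) {
    x <- replicates[[oc]]
    x <- x[!is.na(x)]
    ci <- .pctl_ci(x)
    data.frame(outcome = oc, mean = mean(x), ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]], p_diff_positive = mean(x > 0),
               stringsAsFactors = FALSE)
  }))
  structure(list(n_reps = n_reps, n_per_arm = n_per_arm,
                 replicates = replicates, summary = summ),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d replicates x %d patients/arm\n",
              x$n_reps, x$n_per_arm))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
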