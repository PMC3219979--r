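# Maximum-likelihood estimation of phase dwell-time distributions from
# right-censored individual-patient records, following the cause-specific
# censoring convention: when fitting the curve of one exit cause, records
# that left through any other cause (or were administratively censored)
# enter the likelihood as censored at their observed dwell time.

# log-likelihood of right-censored Weibull data on the (log L, log p) scale
.wb_loglik <- function(logL, logp, t_all, ev) {
  L <- exp(logL); p <- exp(logp)
  te <- t_all[ev]
  sum(log(p) + p * (logL + log(te)) - log(te)) - sum((L * t_all)^p)
}

.wb_grad <- function(logL, logp, t_all, ev) {
  L <- exp(logL); p <- exp(logp)
  ne <- sum(ev)
  lt <- logL + log(t_all)        # log(L t)
  Hp <- (L * t_all)^p
  dlogL <- p * (ne - sum(Hp))
  dp <- ne / p + sum(lt[ev]) - sum(Hp * lt)
  c(dlogL, dp * p)
}

#' Fit a Weibull dwell-time distribution under right censoring
#'
#' Maximises the right-censored Weibull log-likelihood
#' \eqn{\sum_{events} \log h(t_i) + \sum_{all} \log S(t_i)} in the
#' parameterisation \eqn{S(t) = \exp[-(Lt)^p]}. Optimisation runs on
#' (log L, log p) to enforce positivity, started from the closed-form
#' exponential estimate of L with shapes 0.5, 1 and 2; the best converged
#' likelihood wins and is polished until the gradient norm on the log
#' scale falls below 1e-8.
#'
#' @param time observed dwell times in hours (positive for events;
#'   censored records may be zero, contributing nothing).
#' @param event logical (or 0/1): TRUE when the exit of the modelled cause
#'   was observed, FALSE when the record is censored -- either
#'   administratively or because the phase ended through a competing
#'   cause.
#' @param fix_p optional fixed shape; when supplied only L is estimated,
#'   using its closed form \eqn{\hat L = (n_{events}/\sum t^p)^{1/p}}.
#' @return a [weibull_params()] object (standard errors unset; see
#'   [bootstrap_weibull()]).
#' @examples
#' set.seed(1)
#' t <- rweibull(500, shape = 1.5, scale = 1 / 0.01)
#' fit_weibull_censored(t, rep(TRUE, 500))
#' @export
fit_weibull_censored <- function(time, event, fix_p = NULL) {
  event <- as.logical(event)
  .assert(length(time) == length(event), "time and event lengths differ")
  .assert(sum(event) >= 2 || (!is.null(fix_p) && sum(event) >= 1),
          "need at least two uncensored events to fit both parameters")
  .assert(all(time[event] > 0), "event times must be positive")
  .assert(all(time >= 0), "times must be nonnegative")
  keep <- time > 0 | event
  time <- time[keep]; event <- event[keep]
  ne <- sum(event)
  if (!is.null(fix_p)) {
    .assert(fix_p > 0, "fix_p must be positive")
    L <- (ne / sum(time^fix_p))^(1 / fix_p)
    return(weibull_params(L, fix_p))
  }
  L0 <- ne / sum(time)                       # exponential closed form
  best <- NULL
  for (p0 in c(0.5, 1, 2)) {
    fit <- tryCatch(optim(
      c(log(L0), log(p0)),
      fn = function(th) -.wb_loglik(th[1], th[2], time, event),
      gr = function(th) -.wb_grad(th[1], th[2], time, event),
      method = "BFGS",
      control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  .assert(!is.null(best), "Weibull optimisation failed")
  # Newton polish on the log scale until gradient norm < 1e-8
  th <- best$par
  for (i in 1:50) {
    g <- .wb_grad(th[1], th[2], time, event)
    if (sqrt(sum(g^2)) < 1e-8) break
    h <- 1e-5
    H <- matrix(0, 2, 2)
    for (j in 1:2) {
      thp <- th; thp[j] <- thp[j] + h
      thm <- th; thm[j] <- thm[j] - h
      H[, j] <- (.wb_grad(thp[1], thp[2], time, event) -
                 .wb_grad(thm[1], thm[2], time, event)) / (2 * h)
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    thn <- th - step
    if (.wb_loglik(thn[1], thn[2], time, event) >=
        .wb_loglik(th[1], th[2], time, event)) th <- thn else break
  }
  weibull_params(exp(th[1]), exp(th[2]))
}

#' Bootstrap standard errors of a censored Weibull fit
#'
#' Resamples patients with replacement `B` times, refits, and attaches the
#' empirical standard deviations of L-hat and p-hat and their Pearson
#' correlation to the full-data point estimates (which are left
#' unchanged). Replicates without any event are discarded; more than 10%
#' discarded aborts with an error.
#'
#' @inheritParams fit_weibull_censored
#' @param B number of bootstrap replicates (default 1000, minimum 100).
#' @param id optional patient identifier per record; resampling is by
#'   patient, so repeated records of one patient stay together.
#' @param seed optional integer seed.
#' @param fix_p optional fixed shape, forwarded to every fit.
#' @return a [weibull_params()] object with `se_L`, `se_p` and `corr_Lp`
#'   filled in.
#' @export
bootstrap_weibull <- function(time, event, B = 1000L, id = NULL,
                              seed = NULL, fix_p = NULL) {
  .assert(B >= 100, "B must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  event <- as.logical(event)
  point <- fit_weibull_censored(time, event, fix_p = fix_p)
  if (is.null(id)) id <- seq_along(time)
  uid <- unique(id)
  Ls <- numeric(0); ps <- numeric(0); dropped <- 0L
  for (b in seq_len(B)) {
    pick <- sample(uid, length(uid), replace = TRUE)
    rows <- unlist(lapply(pick, function(u) which(id == u)), use.names = FALSE)
    tb <- time[rows]; eb <- event[rows]
    if (sum(eb) < 2) { dropped <- dropped + 1L; next }
    fit <- tryCatch(fit_weibull_censored(tb, eb, fix_p = fix_p),
                    error = function(e) NULL)
    if (is.null(fit)) { dropped <- dropped + 1L; next }
    Ls <- c(Ls, fit$L); ps <- c(ps, fit$p)
  }
  if (dropped > 0)
    message(sprintf("bootstrap: %d of %d replicates without events discarded",
                    dropped, B))
  .assert(dropped <= 0.1 * B,
          "more than 10% of bootstrap replicates had no events")
  se_L <- sd(Ls); se_p <- sd(ps)
  corr <- if (se_L > 0 && se_p > 0) cor(Ls, ps) else 0
  weibull_params(point$L, point$p, se_L = se_L, se_p = se_p, corr_Lp = corr)
}

#' Constant hourly probability matching an observed event rate
#'
#' For states where events are too scarce for a survival curve, the model
#' uses the flat hourly probability whose implied exponential rate
#' reproduces the observed occurrence rate:
#' `1 - exp(-n_events / exposure_hours)`.
#'
#' @param n_events number of events observed.
#' @param exposure_hours total person-hours at risk.
#' @return list with `hourly_prob` and its delta-method `se`
#'   (`sqrt(n_events)/exposure * exp(-rate)`).
#' @export
estimate_constant_hazard <- function(n_events, exposure_hours) {
  .assert(n_events >= 0 && exposure_hours > 0,
          "need n_events >= 0 and exposure_hours > 0")
  r <- n_events / exposure_hours
  list(hourly_prob = -expm1(-r),
       se = sqrt(n_events) / exposure_hours * exp(-r))
}

#' Fraction of instantaneous transitions in an eligible state
#'
#' @param dwells nonnegative dwell times; exact zeros are the patients who
#'   passed through instantly.
#' @return fraction of zeros (the positive dwells are fitted separately
#'   with [fit_weibull_censored()]).
#' @export
estimate_zero_dwell_fraction <- function(dwells) {
  .assert(length(dwells) > 0 && all(dwells >= 0),
          "dwells must be a nonempty nonnegative vector")
  mean(dwells == 0)
}

#' Mean daily drug doses by arm, phase and drug
#'
#' @param records data.frame with columns `patient_id`, `arm`, `phase`
#'   (`before_weaning`/`during_weaning`), `drug`, `total_mg_per_day`.
#' @return data.frame with one row per (arm, phase, drug): `n`,
#'   `mean_mg_per_day`, `se` (standard error of the mean; 0 for a single
#'   patient).
#' @export
mean_daily_doses <- function(records) {
  .assert(all(c("patient_id", "arm", "phase", "drug", "total_mg_per_day")
              %in% names(records)), "missing dose-record columns")
  .assert(all(records$total_mg_per_day >= 0), "doses must be nonnegative")
  agg <- aggregate(total_mg_per_day ~ arm + phase + drug, data = records,
                   FUN = function(x) c(n = length(x), mean = mean(x),
                                       se = if (length(x) > 1)
                                         sd(x) / sqrt(length(x)) else 0))
  out <- data.frame(agg[c("arm", "phase", "drug")],
                    n = agg$total_mg_per_day[, "n"],
                    mean_mg_per_day = agg$total_mg_per_day[, "mean"],
                    se = agg$total_mg_per_day[, "se"])
  out[order(out$arm, out$phase, out$drug), ]
}

# cause-specific (time, event) extraction: event TRUE when the record
# exited through `cause`; anything else is censored at its dwell time
.cause_data <- function(rec, cause) {
  list(time = rec$dwell_hours, event = rec$exit_event == cause,
       id = rec$patient_id)
}

#' Estimate the full model parameter set from trial records
#'
#' Runs the complete estimation pipeline on individual-patient phase
#' records (as produced by [generate_trial()] or read from CSV):
#' per-arm Weibulls for maintenance progression and weaning duration,
#' a pooled maintenance death Weibull, the remifentanil time-to-switch
#' Weibull, per-arm zero-dwell fractions and dwell Weibulls for the
#' MV "eligible" states (pooled post-extubation), pooled post-extubation
#' progression, and constant hourly death probabilities during weaning
#' and post-extubation. With `B > 0`, every Weibull also gets bootstrap
#' standard errors and the L-p correlation.
#'
#' @param phase_records data.frame with columns `patient_id`, `arm`,
#'   `state`, `dwell_hours`, `exit_event`
#'   (`progress`/`death`/`switch`/`censored`).
#' @param B bootstrap replicates per Weibull (0 = point estimates only).
#' @param seed optional integer seed for the bootstrap.
#' @return a [model_params()] object.
#' @export
estimate_trial_params <- function(phase_records, B = 0L, seed = NULL) {
  rec <- phase_records
  .assert(all(c("patient_id", "arm", "state", "dwell_hours", "exit_event")
              %in% names(rec)), "missing phase-record columns")
  if (!is.null(seed)) set.seed(seed)
  fit1 <- function(sub, cause) {
    d <- .cause_data(sub, cause)
    pos <- d$time > 0 | d$event   # zero-dwell censored records carry no info
    if (B > 0)
      bootstrap_weibull(d$time[pos], d$event[pos], B = B, id = d$id[pos])
    else fit_weibull_censored(d$time[pos], d$event[pos])
  }
  s1 <- rec[rec$state == 1L, ]
  s1_progress <- list(CS = fit1(s1[s1$arm == "CS", ], "progress"),
                      RS = fit1(s1[s1$arm == "RS", ], "progress"))
  s1_death <- fit1(s1, "death")               # pooled across arms
  s1_switch <- fit1(s1[s1$arm == "RS", ], "switch")
  fit_eligible <- function(sub) {
    zf <- estimate_zero_dwell_fraction(sub$dwell_hours)
    pos <- sub[sub$dwell_hours > 0, ]
    dwell <- if (zf < 1 && sum(pos$exit_event == "progress") >= 2)
      fit1(pos, "progress") else NULL
    list(zero_fraction = zf,
         zero_fraction_se = sqrt(zf * (1 - zf) / nrow(sub)),
         dwell = dwell)
  }
  s2cs <- fit_eligible(rec[rec$state == 2L & rec$arm == "CS", ])
  s2rs <- fit_eligible(rec[rec$state == 2L & rec$arm == "RS", ])
  s4cs <- fit_eligible(rec[rec$state == 4L & rec$arm == "CS", ])
  s4rs <- fit_eligible(rec[rec$state == 4L & rec$arm == "RS", ])
  s6 <- fit_eligible(rec[rec$state == 6L, ])  # pooled post-extubation
  s3 <- rec[rec$state == 3L, ]
  s3_progress <- list(CS = fit1(s3[s3$arm == "CS", ], "progress"),
                      RS = fit1(s3[s3$arm == "RS", ], "progress"))
  s3_death <- estimate_constant_hazard(sum(s3$exit_event == "death"),
                                       sum(s3$dwell_hours))
  s5 <- rec[rec$state == 5L, ]
  s5_progress <- fit1(s5, "progress")         # pooled
  s5_death <- estimate_constant_hazard(sum(s5$exit_event == "death"),
                                       sum(s5$dwell_hours))
  model_params(
    s1_progress = s1_progress, s1_death = s1_death, s1_switch = s1_switch,
    s2 = list(zero_fraction = c(CS = s2cs$zero_fraction,
                                RS = s2rs$zero_fraction),
              zero_fraction_se = c(CS = s2cs$zero_fraction_se,
                                   RS = s2rs$zero_fraction_se),
              dwell = list(CS = s2cs$dwell, RS = s2rs$dwell)),
    s3_progress = s3_progress, s3_death = s3_death,
    s4 = list(zero_fraction = c(CS = s4cs$zero_fraction,
                                RS = s4rs$zero_fraction),
              zero_fraction_se = c(CS = s4cs$zero_fraction_se,
                                   RS = s4rs$zero_fraction_se),
              dwell = list(CS = s4cs$dwell, RS = s4rs$dwell)),
    s5_progress = s5_progress, s5_death = s5_death,
    s6 = list(zero_fraction = s6$zero_fraction,
              zero_fraction_se = s6$zero_fraction_se, dwell = s6$dwell))
}
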