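# Hour-by-hour semi-Markov engine.
#
# Each phase runs on its own clock (reset to zero at state entry); hour t
# is the interval (t-1, t]. Within an hour, competing exits are resolved
# as sequential conditional Bernoulli draws in the fixed priority order
# death -> switch -> progression. Rather than drawing one Bernoulli per
# hour, the engine inverts the cumulative distribution of the hour of
# first exit (an exact equivalent) so that whole batches of patients can
# be advanced with vectorised arithmetic.

# Sample exit hour and cause for a batch of patients sharing one
# transition table. clock0 = phase clock already elapsed on entry (only
# nonzero for regimen switchers who keep their maintenance clock);
# budget = hours remaining until the 672-hour horizon.
.sample_phase_batch <- function(tab, clock0, budget) {
  n <- length(clock0)
  eff <- attr(tab, "eff")
  total <- attr(tab, "total")
  cumF <- attr(tab, "cumF")
  Scum <- attr(tab, "Scum")
  H <- nrow(tab)
  dwell <- integer(n)
  cause <- rep(NA_character_, n)
  zf <- attr(tab, "zero_fraction")
  todo <- seq_len(n)
  if (!is.null(zf)) {
    z <- runif(n) < zf
    dwell[z] <- 0L
    cause[z] <- "progress"            # instantaneous pass-through
    todo <- which(!z)
  }
  if (length(todo)) {
    U <- runif(length(todo))
    S0 <- ifelse(clock0[todo] > 0L, Scum[pmin(clock0[todo], H)], 1)
    ctar <- 1 - S0 * (1 - U)
    # first hour t with cumF[t] >= ctar
    t_exit <- findInterval(ctar, cumF, left.open = TRUE) + 1L
    d <- t_exit - clock0[todo]
    cens <- t_exit > H | d > budget[todo]
    dwell[todo] <- as.integer(ifelse(cens, budget[todo], d))
    ok <- todo[!cens]
    if (length(ok)) {
      tt <- t_exit[!cens]
      u2 <- runif(length(ok)) * total[tt]
      k <- ncol(eff)
      cidx <- rep(1L, length(ok))
      if (k >= 2) {
        cum <- eff
        for (j in 2:k) cum[, j] <- cum[, j] + cum[, j - 1]
        for (j in 2:k) cidx[u2 > cum[tt, j - 1]] <- j
      }
      cause[ok] <- colnames(eff)[cidx]
    }
  }
  list(dwell = dwell, cause = cause)
}

# Simulate one arm of n patients. specs = build_phase_specs() output for
# both arms (switchers continue under the CS tables). Returns per-patient
# summary and the segment table.
.simulate_arm <- function(n, arm, specs, horizon = 672L) {
  tabs <- new.env(parent = emptyenv())
  get_tab <- function(s, a) {
    key <- paste0(s, a)
    if (is.null(tabs[[key]]))
      tabs[[key]] <- build_transition_table(specs[[a]][[s]], horizon)
    tabs[[key]]
  }
  state <- rep(1L, n)
  tnow <- rep(0L, n)
  clock <- rep(0L, n)
  sed_arm <- rep(arm, n)
  switched_at <- rep(NA_integer_, n)
  weaning_start <- rep(NA_integer_, n)
  terminal <- rep(NA_character_, n)
  seg_id <- list(); seg_state <- list(); seg_in <- list(); seg_out <- list()
  push_seg <- function(ids, s, a, b) {
    i <- length(seg_id) + 1L
    seg_id[[i]] <<- ids; seg_state[[i]] <<- rep(s, length(ids))
    seg_in[[i]] <<- a; seg_out[[i]] <<- b
  }
  for (s in 1:6) {
    repeat {
      idx <- which(state == s & is.na(terminal))
      if (!length(idx)) break
      for (a in c("CS", "RS")) {
        gi <- idx[sed_arm[idx] == a]
        if (!length(gi)) next
        tab <- get_tab(s, a)
        res <- .sample_phase_batch(tab, clock[gi], horizon - tnow[gi])
        entry <- tnow[gi]
        exit <- entry + res$dwell
        push_seg(gi, s, entry, exit)
        tnow[gi] <- exit
        cz <- res$cause
        dests <- attr(tab, "destinations")
        # censored at horizon
        cens <- is.na(cz)
        terminal[gi[cens]] <- "horizon_censored"
        # death
        dd <- !cens & cz == "death"
        terminal[gi[dd]] <- "death"
        state[gi[dd]] <- STATE_DEATH
        # switch: stay in state, keep phase clock, continue under CS
        sw <- !cens & cz == "switch"
        if (any(sw)) {
          wi <- gi[sw]
          switched_at[wi] <- tnow[wi]
          sed_arm[wi] <- "CS"
          clock[wi] <- clock[wi] + res$dwell[sw]
        }
        # progression
        pr <- !cens & cz == "progress"
        if (any(pr)) {
          pi <- gi[pr]
          d_pr <- rep(dests[["progress"]], length(pi))
          state[pi] <- d_pr
          clock[pi] <- 0L
          w3 <- pi[d_pr == 3L]
          weaning_start[w3] <- tnow[w3]
          done <- pi[state[pi] == STATE_DISCHARGED]
          terminal[done] <- "discharged"
        }
      }
    }
  }
  segments <- data.frame(
    id = unlist(seg_id) %||% integer(0),
    state = unlist(seg_state) %||% integer(0),
    entry = unlist(seg_in) %||% integer(0),
    exit = unlist(seg_out) %||% integer(0))
  segments <- segments[order(segments$id, segments$entry, segments$state), ]
  rownames(segments) <- NULL
  hours_mv <- rowsum(
    (segments$exit - segments$entry) * (segments$state <= 4L),
    segments$id)[, 1]
  hours_icu <- rowsum(
    (segments$exit - segments$entry) * (segments$state <= 6L),
    segments$id)[, 1]
  patients <- data.frame(
    id = seq_len(n), arm = arm,
    hours_mv = hours_mv[as.character(seq_len(n))],
    hours_icu = hours_icu[as.character(seq_len(n))],
    switched_at = switched_at,
    weaning_start_hour = weaning_start,
    terminal = terminal, stringsAsFactors = FALSE)
  list(patients = patients, segments = segments)
}

#' Simulate a single patient trajectory
#'
#' Runs one patient through the hourly state machine: starting in
#' MV-maintenance at hour 0, each hour the competing exits of the current
#' state are evaluated (death first, then regimen switch, then
#' progression); "eligible" states are passed instantly with their
#' zero-dwell probability; a remifentanil patient who switches continues
#' the maintenance phase under conventional-regimen dynamics without
#' resetting the phase clock. Simulation ends at discharge, death, or the
#' 672-hour horizon (administrative censoring).
#'
#' @param arm `"CS"` or `"RS"`.
#' @param specs output of [build_phase_specs()] (both arms are required:
#'   switchers continue under the CS tables).
#' @param horizon hours of follow-up (default 672 = 28 days).
#' @return An object of class `patient_history`: list with `patient_id`,
#'   `arm_initial`, `segments` (data.frame state/entry/exit, zero-length
#'   rows marking instantaneous pass-throughs), `switched_at`,
#'   `weaning_start_hour` and `terminal`
#'   (`discharged`/`death`/`horizon_censored`).
#' @examples
#' specs <- build_phase_specs(demo_params())
#' set.seed(1)
#' simulate_patient("RS", specs)
#' @export
simulate_patient <- function(arm, specs, horizon = 672L) {
  arm <- match.arg(arm, c("CS", "RS"))
  .assert(all(c("CS", "RS") %in% names(specs)),
          "specs must contain both arms (use build_phase_specs())")
  sim <- .simulate_arm(1L, arm, specs, horizon)
  p <- sim$patients
  structure(list(
    patient_id = 1L, arm_initial = arm,
    segments = sim$segments[, c("state", "entry", "exit")],
    switched_at = p$switched_at, weaning_start_hour = p$weaning_start_hour,
    terminal = p$terminal), class = "patient_history")
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("<patient_history> arm %s, terminal %s%s\n", x$arm_initial,
              x$terminal,
              if (!is.na(x$switched_at))
                sprintf(", switched to CS at hour %d", x$switched_at) else ""))
  print(x$segments)
  invisible(x)
}

#' Simulate a two-arm cohort and aggregate its outcomes
#'
#' Simulates `n_per_arm` patients per regimen, accumulates per-patient
#' costs, and reports mean and median length of stay on mechanical
#' ventilation (hours in states 1--4 / 24), in the ICU (states 1--6 / 24),
#' and mean total 28-day cost per arm, together with the conventional
#' minus remifentanil differences.
#'
#' @param n_per_arm patients per arm (default 10000, which keeps the Monte
#'   Carlo noise of the mean LOS below about 0.05 day).
#' @param params a [model_params()] object (or a prebuilt
#'   [build_phase_specs()] list).
#' @param costs a [cost_params()] object.
#' @param seed optional integer seed; same seed gives identical results.
#' @param horizon follow-up hours (default 672).
#' @param common_rng if TRUE both arms reuse the same random number
#'   stream (common random numbers), so identical specifications give
#'   identical arms.
#' @param keep_histories if TRUE the per-segment trajectory table is
#'   retained in the result.
#' @return An object of class `cohort_result`: list with `patients`
#'   (per-patient data.frame including `cost_eur`), `arms` (per-arm
#'   summary data.frame), `diff` (named CS-RS differences `los_icu_days`,
#'   `los_mv_days`, `cost_eur`), and optionally `segments`.
#' @examples
#' res <- run_cohort(500, demo_params(), seed = 1)
#' res$diff
#' @export
run_cohort <- function(n_per_arm, params, costs = default_cost_params(),
                       seed = NULL, horizon = 672L, common_rng = FALSE,
                       keep_histories = FALSE) {
  .assert(n_per_arm >= 1, "n_per_arm must be >= 1")
  specs <- if (inherits(params, "model_params"))
    build_phase_specs(params) else params
  if (!is.null(seed)) set.seed(seed)
  sims <- list()
  for (a in c("CS", "RS")) {
    if (common_rng && !is.null(seed)) set.seed(seed)
    sims[[a]] <- .simulate_arm(n_per_arm, a, specs, horizon)
  }
  pats <- list(); segs <- list()
  off <- 0L
  for (a in c("CS", "RS")) {
    p <- sims[[a]]$patients; s <- sims[[a]]$segments
    p$cost_eur <- .cohort_costs(s, p, costs)
    p$id <- p$id + off; s$id <- s$id + off
    off <- off + n_per_arm
    pats[[a]] <- p; segs[[a]] <- s
  }
  patients <- do.call(rbind, pats)
  rownames(patients) <- NULL
  out <- .aggregate_cohort(patients)
  if (keep_histories) out$segments <- do.call(rbind, segs)
  out
}

.aggregate_cohort <- function(patients) {
  summarise_arm <- function(p) data.frame(
    arm = p$arm[1], n = nrow(p),
    mean_los_icu_days = mean(p$hours_icu) / 24,
    median_los_icu_days = median(p$hours_icu) / 24,
    mean_los_mv_days = mean(p$hours_mv) / 24,
    median_los_mv_days = median(p$hours_mv) / 24,
    mean_cost_eur = mean(p$cost_eur),
    stringsAsFactors = FALSE)
  arms <- rbind(summarise_arm(patients[patients$arm == "RS", ]),
                summarise_arm(patients[patients$arm == "CS", ]))
  rownames(arms) <- NULL
  cs <- arms[arms$arm == "CS", ]; rs <- arms[arms$arm == "RS", ]
  diff <- c(los_icu_days = cs$mean_los_icu_days - rs$mean_los_icu_days,
            los_mv_days = cs$mean_los_mv_days - rs$mean_los_mv_days,
            cost_eur = cs$mean_cost_eur - rs$mean_cost_eur)
  structure(list(patients = patients, arms = arms, diff = diff),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  print(x$arms, digits = 4)
  cat("CS - RS differences:\n")
  print(round(x$diff, 3))
  invisible(x)
}

#' On-label subgroup: weaning started within 72 hours
#'
#' Restricts a cohort to the patients in whom weaning (entry into state 3)
#' began within 72 hours of model entry -- the subgroup matching the
#' licensed three-day use of remifentanil -- and re-aggregates the
#' outcomes.
#'
#' @param cohort a `cohort_result` from [run_cohort()].
#' @param cutoff_hours inclusion boundary, default 72 (inclusive).
#' @return A `cohort_result` for the subgroup, or `NULL` (with a message)
#'   when the subgroup is empty in either arm.
#' @export
onlabel_subgroup <- function(cohort, cutoff_hours = 72) {
  .assert(inherits(cohort, "cohort_result"), "cohort must be a cohort_result")
  p <- cohort$patients
  keep <- !is.na(p$weaning_start_hour) & p$weaning_start_hour <= cutoff_hours
  sub <- p[keep, , drop = FALSE]
  if (!all(c("CS", "RS") %in% sub$arm)) {
    message("on-label subgroup is empty in at least one arm; nothing to report")
    return(NULL)
  }
  .aggregate_cohort(sub)
}
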