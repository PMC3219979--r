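#' Exit causes from a health state
#'
#' A non-absorbing state is left through one of up to three competing
#' causes: progression to the next state, death, or (remifentanil
#' maintenance only) a switch to the conventional regimen. Each cause is
#' described by one of three hazard kinds:
#'
#' * `exit_weibull()` -- a time-dependent hazard derived from a Weibull
#'   dwell-time curve;
#' * `exit_constant()` -- a flat hourly probability (used for death during
#'   weaning and post-extubation, where observed deaths are too scarce to
#'   support a survival curve);
#' * `exit_zero_dwell()` -- a point mass at zero dwell (an instantaneous
#'   pass-through with probability `zero_fraction`, resolved on state
#'   entry) mixed with a Weibull for the patients who do stay.
#'
#' @param destination state id the cause leads to.
#' @param w a [weibull_params()] object (may be NULL in
#'   `exit_zero_dwell()` when every patient passes through instantly).
#' @param hourly_prob constant per-hour exit probability in \[0, 1\].
#' @param zero_fraction probability in \[0, 1\] of a zero dwell.
#' @return An object of class `exit_cause`.
#' @name exit_cause
NULL

.new_exit <- function(kind, destination, ...) {
  .assert(destination %in% 1:8, "destination must be a state id 1-8")
  structure(list(kind = kind, destination = as.integer(destination), ...),
            class = "exit_cause")
}

#' @rdname exit_cause
#' @export
exit_weibull <- function(destination, w) {
  .assert(inherits(w, "weibull_params"), "w must be a weibull_params object")
  .new_exit("weibull", destination, weibull = w)
}

#' @rdname exit_cause
#' @export
exit_constant <- function(destination, hourly_prob) {
  .assert(is.numeric(hourly_prob) && length(hourly_prob) == 1 &&
            hourly_prob >= 0 && hourly_prob <= 1,
          "hourly_prob must be a probability in [0, 1]")
  .new_exit("constant_hazard", destination, hourly_prob = hourly_prob)
}

#' @rdname exit_cause
#' @export
exit_zero_dwell <- function(destination, zero_fraction, w = NULL) {
  .assert(is.numeric(zero_fraction) && length(zero_fraction) == 1 &&
            zero_fraction >= 0 && zero_fraction <= 1,
          "zero_fraction must be a probability in [0, 1]")
  .assert(is.null(w) || inherits(w, "weibull_params"),
          "w must be NULL or a weibull_params object")
  .assert(!is.null(w) || zero_fraction == 1,
          "a Weibull component is required unless zero_fraction is 1")
  .new_exit("zero_dwell_mixture", destination, zero_fraction = zero_fraction,
            weibull = w)
}

# fixed within-hour priority order for competing exits
.CAUSE_PRIORITY <- c("death", "switch", "progress")

#' Per-(state, arm) transition specification
#'
#' Bundles the competing exit causes of one health state under one
#' treatment arm. Only state 1 under the remifentanil arm may carry a
#' `switch` exit; absorbing states carry none; every other state must have
#' a `progress` exit.
#'
#' @param state state id (1--6 for states with exits).
#' @param arm `"CS"` or `"RS"`.
#' @param exits named list of [exit_cause] objects; names from
#'   `c("progress", "death", "switch")`.
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(state, arm, exits) {
  arm <- match.arg(arm, c("CS", "RS"))
  state <- as.integer(state)
  .assert(state %in% 1:6, "only states 1-6 have exits")
  .assert(is.list(exits) && length(exits) >= 1 &&
            all(names(exits) %in% .CAUSE_PRIORITY),
          "exits must be a named list with names among progress/death/switch")
  .assert(all(vapply(exits, inherits, TRUE, "exit_cause")),
          "every exit must be an exit_cause object")
  .assert("progress" %in% names(exits),
          "every non-absorbing state needs a progression exit")
  if ("switch" %in% names(exits))
    .assert(state == 1L && arm == "RS",
            "a switch exit is only allowed for state 1 under RS")
  # priority order death -> switch -> progress, applied within each hour
  exits <- exits[order(match(names(exits), .CAUSE_PRIORITY))]
  structure(list(state = state, arm = arm, exits = exits),
            class = "phase_spec")
}

#' Precompute the hourly transition table of one phase
#'
#' Evaluates, for each hour 1..`horizon` on the phase clock, the naive
#' hourly probability of each competing exit cause (rows of the returned
#' matrix, causes in priority order death, switch, progress). Should a
#' row's naive sum exceed 1 -- possible only under extreme sensitivity-
#' analysis draws -- the row is renormalised proportionally and a warning
#' is emitted. The matrix carries attributes used by the simulation
#' engine: the effective (sequential-conditional) per-cause probabilities,
#' the total per-hour exit probability, its cumulative distribution, and
#' the zero-dwell pass-through fraction of the state, if any.
#'
#' @param spec a [phase_spec()].
#' @param horizon integer number of hours (default 672 = 28 days).
#' @return A `horizon` x n_exits numeric matrix with attributes
#'   `destinations`, `zero_fraction`, `zero_destination`, `eff`, `total`,
#'   `cumF`, `Scum`, `state`, `arm`.
#' @export
build_transition_table <- function(spec, horizon = 672L) {
  .assert(inherits(spec, "phase_spec"), "spec must be a phase_spec")
  horizon <- as.integer(horizon)
  .assert(horizon >= 1, "horizon must be >= 1")
  hrs <- seq_len(horizon)
  cols <- lapply(spec$exits, function(ex) {
    switch(ex$kind,
      weibull = hourly_transition_prob(hrs, ex$weibull),
      constant_hazard = rep(ex$hourly_prob, horizon),
      zero_dwell_mixture =
        if (is.null(ex$weibull)) rep(0, horizon)
        else hourly_transition_prob(hrs, ex$weibull)
    )
  })
  tab <- do.call(cbind, cols)
  colnames(tab) <- names(spec$exits)
  rs <- rowSums(tab)
  if (any(rs > 1)) {
    warning(sprintf(
      "state %d/%s: naive competing-exit probabilities exceed 1 at %d hour(s); renormalising proportionally",
      spec$state, spec$arm, sum(rs > 1)))
    bad <- rs > 1
    tab[bad, ] <- tab[bad, , drop = FALSE] / rs[bad]
  }
  # sequential conditional Bernoulli in priority order:
  # eff_k = q_k * prod_{j<k} (1 - q_j); total = 1 - prod_k (1 - q_k)
  eff <- tab
  keep <- rep(1, horizon)
  for (k in seq_len(ncol(tab))) {
    eff[, k] <- tab[, k] * keep
    keep <- keep * (1 - tab[, k])
  }
  total <- 1 - keep
  Scum <- cumprod(keep)
  zf <- NULL
  zdest <- NA_integer_
  for (nm in names(spec$exits)) {
    ex <- spec$exits[[nm]]
    if (ex$kind == "zero_dwell_mixture") {
      zf <- ex$zero_fraction
      zdest <- ex$destination
    }
  }
  structure(tab,
            destinations = vapply(spec$exits, `[[`, 1L, "destination"),
            zero_fraction = zf, zero_destination = zdest,
            eff = eff, total = total, cumF = 1 - Scum, Scum = Scum,
            state = spec$state, arm = spec$arm)
}

#' Tidy export of all transition tables
#'
#' Flattens the hourly transition probabilities of every (state, arm, exit
#' cause) into a long data.frame suitable for CSV export or plotting
#' hazard curves.
#'
#' @param params a [model_params()] object.
#' @param horizon hours to tabulate (default 672).
#' @return data.frame with columns state, state_label, arm, exit_cause,
#'   hour, probability.
#' @export
transition_table_tidy <- function(params, horizon = 672L) {
  specs <- build_phase_specs(params)
  labs <- health_states()$label
  out <- list()
  for (arm in c("CS", "RS")) {
    for (s in 1:6) {
      tab <- build_transition_table(specs[[arm]][[s]], horizon)
      for (cz in colnames(tab)) {
        out[[length(out) + 1L]] <- data.frame(
          state = s, state_label = labs[s], arm = arm, exit_cause = cz,
          hour = seq_len(nrow(tab)), probability = tab[, cz],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
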