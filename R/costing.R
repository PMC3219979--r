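#' Drug unit costs (2006 Dutch hospital prices)
#'
#' Euro per milligram as paid by the hospital pharmacies in the
#' micro-costing study, price level 2006.
#'
#' @return named numeric vector of euros per mg.
#' @export
unit_costs_2006 <- function() {
  c(morphine = 0.02, midazolam = 0.035, fentanyl = 0.35, lorazepam = 0.04,
    sufentanil_forte = 25, propofol = 0.02, remifentanil = 7.71)
}

#' Hourly sedation cost from mean daily doses
#'
#' Translates mean daily drug consumption (mg/day) into an hourly sedation
#' cost: `sum(dose * price) / 24`.
#'
#' @param daily_doses named numeric vector of mg/day; names must be drugs
#'   present in `unit_costs`.
#' @param unit_costs named euros-per-mg vector, default [unit_costs_2006()].
#' @return euros per hour (single number).
#' @examples
#' # conventional arm, before weaning
#' sedation_cost_per_hour(c(morphine = 71.7, midazolam = 194.2,
#'   fentanyl = 0.8, lorazepam = 2.9, sufentanil_forte = 0.05,
#'   propofol = 1057.4))
#' @export
sedation_cost_per_hour <- function(daily_doses, unit_costs = unit_costs_2006()) {
  .assert(is.numeric(daily_doses) && !is.null(names(daily_doses)),
          "daily_doses must be a named numeric vector")
  .assert(all(daily_doses >= 0), "doses must be nonnegative")
  unknown <- setdiff(names(daily_doses), names(unit_costs))
  if (length(unknown))
    stop("unknown drug(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(daily_doses * unit_costs[names(daily_doses)]) / 24
}

#' Cost inputs of the model
#'
#' Hourly sedation cost by arm and treatment phase, and cost per ICU day
#' with and without mechanical ventilation, each with a standard error for
#' the sensitivity analysis. Defaults are the 2006 base-case inputs:
#' sedation before weaning 1.30 (CS) / 7.47 (RS) euro per hour, during
#' weaning 0.41 / 3.85; ICU day 2106 euro on MV, 1645 off MV.
#'
#' @param sed_before,sed_during named `c(CS = , RS = )` euro/hour.
#' @param sed_before_se,sed_during_se their standard errors.
#' @param icu_day_mv,icu_day_nomv euro per ICU day with / without MV.
#' @param icu_day_mv_se,icu_day_nomv_se their standard errors.
#' @return object of class `cost_params`.
#' @export
cost_params <- function(sed_before = c(CS = 1.30, RS = 7.47),
                        sed_during = c(CS = 0.41, RS = 3.85),
                        sed_before_se = c(CS = 0.13, RS = 0.27),
                        sed_during_se = c(CS = 0.12, RS = 0.41),
                        icu_day_mv = 2106, icu_day_mv_se = 102,
                        icu_day_nomv = 1645, icu_day_nomv_se = 107) {
  sed_before <- unlist(sed_before); sed_during <- unlist(sed_during)
  sed_before_se <- unlist(sed_before_se); sed_during_se <- unlist(sed_during_se)
  .assert(all(c("CS", "RS") %in% names(sed_before)) &&
            all(c("CS", "RS") %in% names(sed_during)),
          "sedation costs need CS and RS entries")
  .assert(all(c(sed_before, sed_during) >= 0) && icu_day_mv > 0 &&
            icu_day_nomv > 0, "costs must be positive")
  structure(list(sed_before = sed_before[c("CS", "RS")],
                 sed_during = sed_during[c("CS", "RS")],
                 sed_before_se = sed_before_se[c("CS", "RS")],
                 sed_during_se = sed_during_se[c("CS", "RS")],
                 icu_day_mv = icu_day_mv, icu_day_mv_se = icu_day_mv_se,
                 icu_day_nomv = icu_day_nomv, icu_day_nomv_se = icu_day_nomv_se),
            class = "cost_params")
}

#' @rdname cost_params
#' @export
default_cost_params <- function() cost_params()

# hourly sedation rate for a (state, arm) pair; zero after extubation
.sed_rate <- function(state, arm, costs) {
  r <- numeric(length(state))
  b <- state %in% .SED_BEFORE_STATES
  d <- state %in% .SED_DURING_STATES
  r[b] <- costs$sed_before[arm[b]]
  r[d] <- costs$sed_during[arm[d]]
  r
}

# hourly ICU bed rate by state
.icu_rate <- function(state, costs) {
  ifelse(state_on_mv(state), costs$icu_day_mv / 24,
         ifelse(state <= 6L, costs$icu_day_nomv / 24, 0))
}

#' Total cost of one simulated patient history
#'
#' Sums, over every hour of the history, the ICU bed cost (MV or non-MV
#' rate according to the current state) and the sedation cost (the
#' before-weaning rate in states 1--2, the during-weaning rate in states
#' 3--4, zero after extubation), using the rates of the regimen the
#' patient is on at that hour: a remifentanil patient who switched accrues
#' conventional-regimen sedation costs from the switch hour onward. Hours
#' after discharge or death cost nothing.
#'
#' @param history a `patient_history` (see [simulate_patient()]) or any
#'   list with elements `segments` (data.frame state/entry/exit),
#'   `arm_initial` and `switched_at`.
#' @param costs a [cost_params()] object.
#' @return total cost in euros.
#' @export
accumulate_costs <- function(history, costs) {
  seg <- history$segments
  if (is.null(seg) || nrow(seg) == 0) return(0)
  seg <- seg[order(seg$entry), , drop = FALSE]
  .assert(all(seg$exit >= seg$entry), "segments must have exit >= entry")
  .assert(seg$entry[1] == 0, "history must start at hour 0")
  if (nrow(seg) > 1)
    .assert(all(abs(seg$entry[-1] - seg$exit[-nrow(seg)]) < 1e-9),
            "segments must be contiguous (no gaps or overlaps)")
  .assert(max(seg$exit) <= 672, "history exceeds the 28-day horizon")
  arm0 <- history$arm_initial
  sw <- history$switched_at
  total <- 0
  for (i in seq_len(nrow(seg))) {
    s <- seg$state[i]; a <- seg$entry[i]; b <- seg$exit[i]
    if (b == a) next
    icu <- .icu_rate(s, costs)
    pieces <- if (identical(arm0, "RS") && !is.na(sw) && a < sw && sw < b)
      list(c(a, sw, 1), c(sw, b, 2)) else if (identical(arm0, "RS") &&
                                              !is.na(sw) && a >= sw)
      list(c(a, b, 2)) else list(c(a, b, 1))
    for (pc in pieces) {
      arm_now <- if (pc[3] == 2) "CS" else arm0
      h <- pc[2] - pc[1]
      total <- total + h * (icu + .sed_rate(s, arm_now, costs))
    }
  }
  total
}

# vectorised costing over a cohort's segment table; relies on segments
# being split at the switch hour (the engine guarantees this)
.cohort_costs <- function(segments, patients, costs) {
  if (nrow(segments) == 0) return(setNames(numeric(nrow(patients)),
                                           patients$id))
  arm0 <- patients$arm[match(segments$id, patients$id)]
  sw <- patients$switched_at[match(segments$id, patients$id)]
  sed_arm <- ifelse(arm0 == "RS" & !is.na(sw) & segments$entry >= sw,
                    "CS", arm0)
  h <- segments$exit - segments$entry
  rate <- .icu_rate(segments$state, costs) +
    .sed_rate(segments$state, sed_arm, costs)
  agg <- rowsum(h * rate, group = segments$id)
  out <- setNames(numeric(nrow(patients)), patients$id)
  out[rownames(agg)] <- agg[, 1]
  out
}
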