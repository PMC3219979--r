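#' Health states of the ICU model
#'
#' The model distinguishes eight health states describing the flow of a
#' mechanically ventilated ICU patient: four states on the ventilator
#' (maintenance, eligible to start weaning, weaning, eligible to extubate),
#' two post-extubation states (post-extubation, eligible for ICU discharge),
#' and two absorbing states (discharged, death). Patients progress through
#' states 1 to 7 in order; death can interrupt the sequence at any point.
#' States 2, 4 and 6 are "eligible" states that a fraction of patients
#' passes through instantaneously.
#'
#' @return A data.frame with columns `id` (1--8), `label`, `on_mv`
#'   (TRUE for states 1--4) and `absorbing` (TRUE for states 7 and 8).
#' @examples
#' health_states()
#' @export
health_states <- function() {
  data.frame(
    id = 1:8,
    label = c(
      "MV-maintenance",
      "MV-eligible-to-wean",
      "MV-weaning",
      "MV-eligible-to-extubate",
      "post-extubation",
      "post-extubation-eligible-discharge",
      "discharged",
      "death"
    ),
    on_mv = c(rep(TRUE, 4), rep(FALSE, 4)),
    absorbing = c(rep(FALSE, 6), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# state id of the two absorbing states
STATE_DISCHARGED <- 7L
STATE_DEATH <- 8L

#' @rdname health_states
#' @param id integer state id(s).
#' @export
state_on_mv <- function(id) id >= 1L & id <= 4L

#' @rdname health_states
#' @export
state_absorbing <- function(id) id == STATE_DISCHARGED | id == STATE_DEATH

# states billed at the before-weaning / during-weaning sedation rate
.SED_BEFORE_STATES <- c(1L, 2L)
.SED_DURING_STATES <- c(3L, 4L)
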