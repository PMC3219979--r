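#' Weibull dwell-time parameters
#'
#' Container for the scale/shape parameterisation used throughout the model:
#' the survivor function of a phase dwell time is
#' \deqn{S(t) = \exp[-(Lt)^p], \quad L, p > 0,}
#' with `L` a rate per hour and `p` the dimensionless shape (`p = 1` is the
#' memoryless exponential; `p > 1` gives an increasing hazard). Bootstrap
#' standard errors of `L` and `p` and their correlation may be attached for
#' use in the probabilistic sensitivity analysis.
#'
#' @param L positive scale (rate per hour).
#' @param p positive shape.
#' @param se_L,se_p nonnegative standard errors (NA when not estimated).
#' @param corr_Lp correlation between the estimators of `L` and `p`,
#'   in \[-1, 1\] (NA when not estimated).
#' @return An object of class `weibull_params`.
#' @examples
#' w <- weibull_params(L = 0.01, p = 1.5)
#' weibull_survival(c(0, 50, 100), w)
#' @export
weibull_params <- function(L, p, se_L = NA_real_, se_p = NA_real_,
                           corr_Lp = NA_real_) {
  .assert(is.numeric(L) && length(L) == 1 && is.finite(L) && L > 0,
          "L must be a single positive number")
  .assert(is.numeric(p) && length(p) == 1 && is.finite(p) && p > 0,
          "p must be a single positive number")
  .assert(is.na(se_L) || se_L >= 0, "se_L must be nonnegative")
  .assert(is.na(se_p) || se_p >= 0, "se_p must be nonnegative")
  .assert(is.na(corr_Lp) || abs(corr_Lp) <= 1, "corr_Lp must lie in [-1, 1]")
  structure(list(L = L, p = p, se_L = se_L, se_p = se_p, corr_Lp = corr_Lp),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(L = %.6g /h, p = %.4g)", x$L, x$p))
  if (!is.na(x$se_L))
    cat(sprintf("  [se_L %.3g, se_p %.3g, corr %.3g]",
                x$se_L, x$se_p, x$corr_Lp))
  cat("\n")
  invisible(x)
}

#' Weibull survivor function
#'
#' @param t nonnegative time(s) in hours.
#' @param w a [weibull_params()] object.
#' @return `exp(-(L t)^p)`, in (0, 1]; `S(0) = 1`.
#' @export
weibull_survival <- function(t, w) {
  .assert(inherits(w, "weibull_params"), "w must be a weibull_params object")
  .assert(is.numeric(t) && all(is.finite(t)) && all(t >= 0),
          "t must be nonnegative")
  exp(-(w$L * t)^w$p)
}

#' Hourly transition probability from a Weibull dwell-time curve
#'
#' Converts the continuous survivor curve into the probability of leaving
#' during hour `t` (the interval (t-1, t] on the phase clock), conditional
#' on still being in the phase at t-1:
#' \deqn{tp(t) = 1 - S(t)/S(t-1).}
#' Computed as `-expm1(-((Lt)^p - (L(t-1))^p))` for numerical stability; for
#' `p = 1` this is the constant `1 - exp(-L)` at every hour.
#'
#' @param t integer hour(s) >= 1 on the phase clock.
#' @param w a [weibull_params()] object.
#' @return probabilities in \[0, 1).
#' @export
hourly_transition_prob <- function(t, w) {
  .assert(inherits(w, "weibull_params"), "w must be a weibull_params object")
  .assert(is.numeric(t) && all(is.finite(t)) && all(t >= 1),
          "t must be >= 1 (hour index on the phase clock)")
  if (w$p == 1) return(rep(-expm1(-w$L), length(t)))  # memoryless, exact
  dH <- (w$L * t)^w$p - (w$L * (t - 1))^w$p
  # keep the result strictly below 1 in double precision even where the
  # cumulative-hazard increment overflows (1 - exp(-36) < 1 < 1 - exp(-37))
  -expm1(-pmin(dH, 36))
}
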