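#' Publication-style results table
#'
#' Arranges cohort and sensitivity-analysis results in the layout of the
#' published comparison: one row each for ICU length of stay, MV length
#' of stay and total 28-day cost, with columns RS, CS, the CS-RS
#' difference, its 95% percentile interval and the probability that the
#' difference is positive. Without a PSA result the interval and
#' probability columns are left empty (with a warning). Days are rounded
#' to one decimal and euros to whole units in the printed table; the
#' returned data.frame keeps full precision in the `*_raw` attribute.
#'
#' @param cohort a `cohort_result` from [run_cohort()] (or
#'   [onlabel_subgroup()]).
#' @param psa optional `psa_result` from [run_psa()].
#' @param use_subgroup_ci if TRUE, use the `sub_diff_*` columns of the
#'   PSA summary (for the on-label table).
#' @return data.frame with columns outcome, RS, CS, difference, ci_lower,
#'   ci_upper, p_diff_positive.
#' @export
render_results_table <- function(cohort, psa = NULL,
                                 use_subgroup_ci = FALSE) {
  .assert(inherits(cohort, "cohort_result"), "cohort must be a cohort_result")
  arms <- cohort$arms
  g <- function(col, arm) arms[[col]][arms$arm == arm]
  tab <- data.frame(
    outcome = c("Length of stay ICU (days)", "Length of stay MV (days)",
                "Costs (EUR)"),
    RS = c(g("mean_los_icu_days", "RS"), g("mean_los_mv_days", "RS"),
           g("mean_cost_eur", "RS")),
    CS = c(g("mean_los_icu_days", "CS"), g("mean_los_mv_days", "CS"),
           g("mean_cost_eur", "CS")),
    difference = unname(cohort$diff[c("los_icu_days", "los_mv_days",
                                      "cost_eur")]),
    ci_lower = NA_real_, ci_upper = NA_real_, p_diff_positive = NA_real_,
    stringsAsFactors = FALSE)
  if (is.null(psa)) {
    warning("no PSA result supplied; interval and probability columns left empty")
  } else {
    pref <- if (use_subgroup_ci) "sub_diff_" else "diff_"
    keys <- paste0(pref, c("los_icu", "los_mv", "cost"))
    s <- psa$summary
    for (i in seq_along(keys)) {
      r <- s[s$outcome == keys[i], ]
      if (nrow(r) == 1) {
        tab$ci_lower[i] <- r$ci_lower
        tab$ci_upper[i] <- r$ci_upper
        tab$p_diff_positive[i] <- r$p_diff_positive
      }
    }
  }
  raw <- tab
  rnd <- c(1, 1, 0)
  for (col in c("RS", "CS", "difference", "ci_lower", "ci_upper"))
    tab[[col]] <- round(tab[[col]], rnd)
  attr(tab, "raw") <- raw
  tab
}

#' Plot the hourly transition-probability curves
#'
#' One panel per source state, one curve per (arm, exit cause), hour on
#' the x axis -- the model's analogue of the published hazard figures.
#' The data behind the plot is exactly [transition_table_tidy()].
#'
#' @param params a [model_params()] object, or a tidy table already
#'   produced by [transition_table_tidy()].
#' @param horizon hours to plot (default 240).
#' @return a ggplot object.
#' @export
plot_transition_curves <- function(params, horizon = 240L) {
  tidy <- if (is.data.frame(params)) params
          else transition_table_tidy(params, horizon)
  ggplot2::ggplot(tidy, ggplot2::aes(
    x = .data$hour, y = .data$probability,
    colour = .data$exit_cause, linetype = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ state_label, scales = "free_y") +
    ggplot2::labs(x = "hour since state entry",
                  y = "hourly transition probability",
                  colour = "exit cause", linetype = "arm") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL

#' Write results tables to CSV
#'
#' @param tab a table from [render_results_table()] (the full-precision
#'   values are written).
#' @param path output file.
#' @export
write_results_csv <- function(tab, path) {
  raw <- attr(tab, "raw") %||% tab
  write.csv(raw, path, row.names = FALSE)
  invisible(path)
}
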