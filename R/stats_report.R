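# Wilson score intervals, strategy summary tables and monotonicity rate
# tables. Analyses are descriptive: no hypothesis tests between strategies.

#' Wilson score confidence interval for a proportion
#'
#' The Wilson interval has good small-sample behavior and sensible bounds
#' at k = 0 (lower bound exactly 0) and k = n (upper bound exactly 1):
#' center \eqn{(\hat p + z^2/2n) / (1 + z^2/n)}, half-width
#' \eqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2} / (1 + z^2/n)}.
#' The default `z` is the exact 97.5% normal quantile
#' (`qnorm(0.975)` = 1.959964); the conventional 1.96 yields identical
#' one-decimal percent display for all tabulated rates.
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param z Standard-normal quantile; default `qnorm(0.975)`.
#' @return One-row tibble with `k`, `n`, `point` (k/n), `lower`, `upper`,
#'   `z`.
#' @export
wilson_ci <- function(k, n, z = stats::qnorm(0.975)) {
  if (!is_scalar_num(k) || !is_scalar_num(n) || n <= 0 || k < 0 || k > n ||
      k != round(k) || n != round(n)) {
    pr_abort("wilson_ci requires integers 0 <= k <= n with n > 0",
             "pr_domain_error")
  }
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    k = as.integer(k), n = as.integer(n), point = p,
    lower = max(0, center - half), upper = min(1, center + half), z = z
  )
}

#' Format a fraction as a percent string with half-up rounding
#'
#' One-decimal percent display with ties rounded up (`0.0745` -> `"7.5"`),
#' matching the convention of the summary tables; raw fractions are always
#' retained in machine output.
#'
#' @param frac Numeric vector of fractions in \[0, 1\].
#' @param digits Decimal places, default 1.
#' @return Character vector of percent values (no `%` sign).
#' @export
format_percent <- function(frac, digits = 1) {
  formatC(round_half_up(frac * 100, digits), format = "f", digits = digits)
}

#' Summarize one routed strategy
#'
#' Collapses a strategy's decisions and selected scored records into one
#' summary row: mean suggested tests, discharge rate, mean safety-net score
#' among discharges only (`NA` when no scenario was discharged), the
#' contraindication/sequence safety-violation rate with its Wilson CI, the
#' mean violation severity, and the mean number of simulated LLM calls.
#'
#' @param sim Result of [simulate_strategy()] (list with `decisions` and
#'   `selected`), or the `selected` tibble alone (must carry
#'   `simulated_calls`).
#' @param z Normal quantile for the Wilson interval.
#' @return One-row tibble.
#' @export
summarize_strategy <- function(sim, z = stats::qnorm(0.975)) {
  selected <- if (is.data.frame(sim)) sim else sim$selected
  if (is.null(selected) || nrow(selected) == 0) {
    pr_abort("cannot summarize an empty decision set", "pr_empty_error")
  }
  n <- nrow(selected)
  disch <- selected$discharge_flag == 1L
  viol_k <- sum(selected$contra_seq_severity_0to3 > 0)
  ci <- wilson_ci(viol_k, n, z)
  tibble::tibble(
    strategy_id = selected$strategy_id[1] %||% NA_character_,
    n = n,
    tests_mean = mean(selected$tests_count),
    discharge_k = sum(disch),
    discharge_rate = mean(disch),
    safety_net_mean_if_discharge = if (any(disch)) {
      mean(selected$safety_net_score_v2[disch])
    } else {
      NA_real_
    },
    safety_violation_k = viol_k,
    safety_violation_rate = ci$point,
    safety_violation_lower = ci$lower,
    safety_violation_upper = ci$upper,
    mean_severity = mean(selected$contra_seq_severity_0to3),
    mean_simulated_calls = mean(selected$simulated_calls)
  )
}

#' Strategy summary table over a scored run log
#'
#' Runs [simulate_strategy()] for each requested strategy over the same
#' scored run log and stacks the [summarize_strategy()] rows into the
#' standard router-simulation summary table (one row per strategy).
#'
#' @param scored Scored run-log tibble ([score_runlog()]).
#' @param strategies Character vector of strategy ids.
#' @param thresholds Threshold list as in [default_thresholds()].
#' @param z Normal quantile for Wilson intervals.
#' @return Tibble with one row per strategy.
#' @export
summarize_strategies <- function(scored,
                                 strategies = c("BASE_HL", "BASE_HS", "BASE_LL",
                                                "BASE_LS", "ROUTER_R1",
                                                "ROUTER_R2_AUDIT",
                                                "ROUTER_R3_ARBITER"),
                                 thresholds = default_thresholds(),
                                 z = stats::qnorm(0.975)) {
  dplyr::bind_rows(lapply(strategies, function(s) {
    cfg <- strategy_config(s,
                           safety_net_threshold = thresholds$safety_net_threshold,
                           admission_min_level = thresholds$admission_min_level)
    summarize_strategy(simulate_strategy(scored, cfg), z = z)
  }))
}

#' Monotonicity violation rates by strategy, with Wilson CIs
#'
#' @param results Counterfactual results tibble ([run_counterfactual()]).
#' @param z Normal quantile for Wilson intervals.
#' @return Tibble with one row per strategy: `k`, `n`, `rate`, `percent`
#'   (one-decimal display string), `lower`, `upper`, `mean_severity`.
#' @export
monotonicity_table <- function(results, z = stats::qnorm(0.975)) {
  if (nrow(results) == 0) {
    return(tibble::tibble(
      strategy_id = character(0), k = integer(0), n = integer(0),
      rate = numeric(0), percent = character(0),
      lower = numeric(0), upper = numeric(0), mean_severity = numeric(0)
    ))
  }
  groups <- split(results, results$strategy_id)
  dplyr::bind_rows(lapply(names(groups), function(s) {
    g <- groups[[s]]
    ci <- wilson_ci(sum(g$violated), nrow(g), z)
    tibble::tibble(
      strategy_id = s, k = ci$k, n = ci$n, rate = ci$point,
      percent = format_percent(ci$point),
      lower = ci$lower, upper = ci$upper,
      mean_severity = mean(g$severity_0to3)
    )
  }))
}

#' Export a table as CSV (UTF-8)
#'
#' @param tbl Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Plot the tests-vs-safety-net routing trade-off
#'
#' Scatter of mean suggested tests (x, lower is leaner) against mean
#' discharge safety-net score (y, higher is more action-oriented) per
#' strategy; the desirable region is the upper left.
#'
#' @param summary_tbl Output of [summarize_strategies()].
#' @return A ggplot object.
#' @export
plot_tradeoff <- function(summary_tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    pr_abort("ggplot2 is required for plotting", "pr_config_error")
  }
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$tests_mean,
                               y = .data$safety_net_mean_if_discharge,
                               label = .data$strategy_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Mean suggested tests",
                  y = "Mean safety-net score (discharges)",
                  title = "Routing trade-off") +
    ggplot2::theme_minimal()
}

#' Plot monotonicity violation rates with Wilson CI whiskers
#'
#' @param mono_tbl Output of [monotonicity_table()].
#' @return A ggplot object.
#' @export
plot_monotonicity <- function(mono_tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    pr_abort("ggplot2 is required for plotting", "pr_config_error")
  }
  ggplot2::ggplot(mono_tbl,
                  ggplot2::aes(x = .data$strategy_id, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Monotonicity violation rate",
                  title = "Counterfactual monotonicity by strategy") +
    ggplot2::theme_minimal()
}
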