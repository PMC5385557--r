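#' Tidy a rule set
#'
#' Flattens the list-column antecedent/consequent itemsets to canonical
#' strings, one row per rule.
#'
#' @param x A `rule_set`.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.rule_set <- function(x, ...) tidy_rules(x)

#' @rdname tidy.rule_set
#' @export
tidy.final_rule_set <- function(x, ...) {
  out <- tidy_rules(x)
  out$key <- x$key
  out
}

#' Tidy / summarise a pipeline run
#'
#' `tidy()` returns the consolidated final rules, one per row;
#' `glance()` returns the one-row run report (record, interval, rule and
#' final-rule counts plus the thresholds used).
#'
#' @param x A `cbpnarm_run` from [mine_database()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cbpnarm_run <- function(x, ...) tidy(x$final)

#' @rdname tidy.cbpnarm_run
#' @export
glance.cbpnarm_run <- function(x, ...) x$report

#' Tidy a support table
#'
#' @param x A `support_table` from [frequent_itemsets()].
#' @param ... Unused.
#' @return A tibble with the itemset keys, sizes, supports and counts.
#' @export
tidy.support_table <- function(x, ...) {
  tibble(key = x$key, size = x$size, support = x$support,
         count = x$count, frequent = x$frequent)
}

#' Plot a rule set
#'
#' Support-confidence scatter, coloured by rule polarity, shaped by the
#' context-adjusted flag.
#'
#' @param object A `rule_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rule_set <- function(object, ...) {
  df <- tidy_rules(object)
  df$polarity <- ifelse(!df$antecedent_negated & !df$consequent_negated,
                        "positive", "negative")
  ggplot2::ggplot(df, ggplot2::aes(x = support, y = confidence,
                                   colour = polarity,
                                   shape = context_adjusted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "support", y = "confidence") +
    ggplot2::theme_minimal()
}

#' Plot a regime comparison
#'
#' Rule count against minimum support, one line per context regime - the
#' standard way to show that abnormal context prunes rules while rule
#' counts fall monotonically in `ms`.
#'
#' @param object A `cbpnarm_compare` from [compare_modes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbpnarm_compare <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = ms, y = n_rules,
                                       colour = regime)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum support", y = "rules mined") +
    ggplot2::theme_minimal()
}

#' Per-interval rule counts of a run
#'
#' @param run A `cbpnarm_run`.
#' @return A ggplot of positive/negative rule counts per interval.
#' @export
plot_rule_counts <- function(run) {
  df <- bind_rows(lapply(run$rulesets, as_tibble))
  if (!nrow(df)) {
    abort("run produced no rules to plot", class = "cbpnarm_error_contract")
  }
  df$polarity <- ifelse(!df$antecedent_negated & !df$consequent_negated,
                        "positive", "negative")
  counts <- df |> count(interval, polarity, name = "n_rules")
  ggplot2::ggplot(counts, ggplot2::aes(x = interval, y = n_rules,
                                       fill = polarity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "time interval", y = "rules mined") +
    ggplot2::theme_minimal()
}
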