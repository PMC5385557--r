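#' Canonical rule identity
#'
#' A rule's identity is its canonically sorted antecedent and consequent
#' tokens plus the polarity flags; support, confidence and interval are
#' excluded, so the same predicate extracted at two intervals shares one
#' key and the key is invariant under term reordering.
#'
#' @param antecedent,consequent Character vectors of item tokens.
#' @param antecedent_negated,consequent_negated Polarity flags.
#' @return Length-1 character key.
#' @examples
#' rule_key(c("Pheh == 1", "Apd == 1"), "MP == 1")
#' @export
rule_key <- function(antecedent, consequent,
                     antecedent_negated = FALSE, consequent_negated = FALSE) {
  paste0(if (antecedent_negated) "!{" else "{", itemset_key(antecedent),
         "} => ",
         if (consequent_negated) "!{" else "{", itemset_key(consequent), "}")
}

#' Keys for every rule of a rule set
#'
#' @param rules A `rule_set` tibble.
#' @return Character vector of [rule_key()] strings, one per rule.
#' @export
rule_keys <- function(rules) {
  if (!nrow(rules)) return(character())
  paste0(ifelse(rules$antecedent_negated, "!{", "{"),
         map_chr(rules$antecedent, itemset_key),
         "} => ",
         ifelse(rules$consequent_negated, "!{", "{"),
         map_chr(rules$consequent, itemset_key), "}")
}

#' Number of distinct intervals extracting a rule
#'
#' A rule appearing twice within one interval counts once: the count is
#' over distinct time intervals whose rule set contains the key.
#'
#' @param key A [rule_key()] string.
#' @param rulesets List of per-interval `rule_set` tibbles.
#' @return Integer count.
#' @export
count_intervals <- function(key, rulesets) {
  if (!length(rulesets)) {
    abort("need at least one rule set", class = "cbpnarm_error_contract")
  }
  ivs <- unlist(lapply(rulesets, function(rs) {
    rs$interval[rule_keys(rs) == key]
  }))
  length(unique(ivs))
}

#' Temporal consolidation of per-interval rule sets
#'
#' Keeps exactly the rule keys extracted at `>= k` distinct time intervals
#' (the paper-of-record procedure for screening out one-off rules).
#' Aggregated support, confidence and interest of a final rule are means
#' over its contributing intervals; the per-interval supports are retained
#' in a list-column.
#'
#' @param rulesets List of per-interval `rule_set` tibbles.
#' @param k Minimum number of distinct contributing intervals (>= 1).
#' @return A `final_rule_set` tibble: `key`, the rule columns,
#'   `interval_count`, `intervals` (list-column), `interval_support`
#'   (list-column), mean `support`, `confidence`, `interest`, and
#'   `context_adjusted` (TRUE if any contributing rule was adjusted).
#' @export
intersect_rulesets <- function(rulesets, k) {
  if (k < 1) abort("k must be >= 1", class = "cbpnarm_error_config")
  all_rules <- bind_rows(lapply(rulesets, as_tibble))
  empty <- tibble(
    key = character(), antecedent = list(), consequent = list(),
    antecedent_negated = logical(), consequent_negated = logical(),
    interval_count = integer(), intervals = list(),
    interval_support = list(), support = double(), confidence = double(),
    interest = double(), context_adjusted = logical()
  )
  if (!nrow(all_rules)) {
    return(structure(empty, class = c("final_rule_set", class(empty))))
  }
  all_rules$key <- rule_keys(all_rules)
  out <- all_rules |>
    group_by(key) |>
    summarise(
      antecedent = antecedent[1],
      consequent = consequent[1],
      antecedent_negated = antecedent_negated[1],
      consequent_negated = consequent_negated[1],
      interval_count = n_distinct(interval),
      intervals = list(sort(unique(interval))),
      interval_support = list(support),
      support = mean(support),
      confidence = mean(confidence),
      interest = mean(interest),
      context_adjusted = any(context_adjusted),
      .groups = "drop"
    ) |>
    filter(interval_count >= k) |>
    arrange(desc(interval_count), desc(support), key)
  structure(out, class = c("final_rule_set", class(empty)))
}

#' @export
print.final_rule_set <- function(x, ...) {
  cat(sprintf("<final_rule_set> %d consolidated rules\n", nrow(x)))
  NextMethod()
}

#' Near-miss diagnostic for consolidation
#'
#' Lists pairs of rule keys with the same consequent and polarity whose
#' antecedents differ by exactly one item (one dropped, added or
#' substituted term). Such near misses often arise when an abnormal
#' context flips a predicate direction; they are reported as a diagnostic
#' and never merged.
#'
#' @param rulesets List of per-interval `rule_set` tibbles.
#' @return Tibble with `key_a`, `key_b` and their distinct-interval counts.
#' @export
near_miss_report <- function(rulesets) {
  all_rules <- bind_rows(lapply(rulesets, as_tibble))
  empty <- tibble(key_a = character(), key_b = character(),
                  intervals_a = integer(), intervals_b = integer())
  if (!nrow(all_rules)) return(empty)
  all_rules$key <- rule_keys(all_rules)
  uniq <- all_rules[!duplicated(all_rules$key), , drop = FALSE]
  grp <- paste0(uniq$antecedent_negated, "|", uniq$consequent_negated, "|",
                map_chr(uniq$consequent, itemset_key))
  rows <- list()
  for (g in split(seq_len(nrow(uniq)), grp)) {
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) {
      for (j in (i + 1):length(g)) {
        a <- uniq$antecedent[[g[i]]]
        b <- uniq$antecedent[[g[j]]]
        dif <- length(setdiff(a, b)) + length(setdiff(b, a))
        if (dif == 1 || (dif == 2 && length(setdiff(a, b)) == 1)) {
          rows[[length(rows) + 1]] <- tibble(
            key_a = uniq$key[g[i]], key_b = uniq$key[g[j]],
            intervals_a = count_intervals(uniq$key[g[i]], rulesets),
            intervals_b = count_intervals(uniq$key[g[j]], rulesets)
          )
        }
      }
    }
  }
  if (length(rows)) bind_rows(rows) else empty
}
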