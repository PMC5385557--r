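#' Bundled temporal-consolidation demonstration
#'
#' A small rule log of ten positive rules extracted from one site at four
#' time intervals (rainfall as the context variable, normal range
#' 100-300 mm, minimum support 3 in absolute counts). Three of the four
#' antecedent variants recur across intervals; one variant was extracted
#' under out-of-range rainfall (450 mm). Consolidating with `k = 3`
#' retains exactly one rule - the classic illustration of why one-off
#' rules, and rules mined under abnormal context, need screening.
#'
#' @return A list with `rulesets` (per-interval `rule_set` tibbles),
#'   `rules` (the flat rule log including the `context_rainfall` column),
#'   `spec` (the rainfall [context_spec()]), and `thresholds`.
#' @examples
#' demo <- consolidation_demo()
#' intersect_rulesets(demo$rulesets, k = 3)
#' @export
consolidation_demo <- function() {
  path <- system.file("extdata", "consolidation_demo_rules.csv",
                      package = "cbpnarm", mustWork = TRUE)
  rules <- read_rules(path)
  flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rulesets <- lapply(sort(unique(rules$interval)), function(iv) {
    new_rule_set(rules[rules$interval == iv, , drop = FALSE])
  })
  list(
    rulesets = rulesets,
    rules = flat,
    spec = context_spec("rainfall", 100, 300),
    thresholds = thresholds(ms = 3, mc = 0.7, mi = 0, k = 3)
  )
}
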