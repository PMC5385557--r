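#' Classify a context value against its normal range
#'
#' Bounds are inclusive: a value exactly at CIV or CFV is within range.
#'
#' @param value Numeric context value(s).
#' @param spec A single-row [context_spec()].
#' @return Character vector: `"below"`, `"within"` or `"above"`.
#' @examples
#' classify_context(c(50, 250, 450), context_spec("rainfall", 100, 300))
#' @export
classify_context <- function(value, spec) {
  ifelse(value < spec$civ, "below",
         ifelse(value > spec$cfv, "above", "within"))
}

#' Context-based support adjustment
#'
#' Implements the four adjustment cases. With `d` the percentage surplus of
#' the context value over the violated bound, relative to the value itself:
#' below range `d = (civ - value) * 100 / value`, above range
#' `d = (value - cfv) * 100 / value`. Positive rules gain support when the
#' context is below range (`new = actual + actual d / 100`) and lose it
#' above range; negative rules move the opposite way. Within range the
#' support is untouched. The adjusted support is clamped to be
#' non-negative, and to at most 1 when the actual support is a fraction.
#'
#' @param actual Non-negative rule support (fraction or count).
#' @param value Positive context value (adjustment divides by it).
#' @param spec A single-row [context_spec()].
#' @param polarity `"positive"` or `"negative"` rule.
#' @return A one-row tibble: `context_name`, `context_value`, `civ`, `cfv`,
#'   `actual_support`, `difference` (percent), `new_support`, `polarity`,
#'   `case_id`.
#' @examples
#' adjusted_support(5, 450, context_spec("rainfall", 100, 300), "positive")
#' @export
adjusted_support <- function(actual, value, spec,
                             polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (any(actual < 0)) {
    abort("actual support must be non-negative", class = "cbpnarm_error_contract")
  }
  if (value <= 0) {
    abort("adjustment undefined for non-positive context value",
          class = "cbpnarm_error_adjustment")
  }
  zone <- classify_context(value, spec)
  d <- switch(zone,
    below = (spec$civ - value) * 100 / value,
    above = (value - spec$cfv) * 100 / value,
    within = 0
  )
  sign <- if (zone == "within") 0
  else if ((zone == "below") == (polarity == "positive")) 1 else -1
  new <- actual + sign * actual * d / 100
  new <- pmax(new, 0)
  new <- ifelse(actual <= 1, pmin(new, 1), new)
  tibble(
    context_name = spec$name,
    context_value = value,
    civ = spec$civ,
    cfv = spec$cfv,
    actual_support = actual,
    difference = d,
    new_support = new,
    polarity = polarity,
    case_id = if (zone == "within") "within-range" else paste(polarity, zone, sep = "-")
  )
}

# multiplicative adjustment factors for one interval's context values,
# composed sequentially over the abnormal variables (a product, hence
# order-independent; any single negative step zeroes the running support)
context_adjustment_factors <- function(record_context, specs) {
  f_pos <- 1
  f_neg <- 1
  steps_pos <- numeric()
  steps_neg <- numeric()
  abnormal <- character()
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    if (!nm %in% names(record_context)) next
    v <- record_context[[nm]]
    if (is.na(v)) next
    zone <- classify_context(v, specs[i, ])
    if (zone == "within") next
    if (v <= 0) {
      warn(sprintf("context '%s' value %g is non-positive; adjustment undefined, variable skipped",
                   nm, v))
      next
    }
    d <- if (zone == "below") (specs$civ[i] - v) * 100 / v
         else (v - specs$cfv[i]) * 100 / v
    s <- if (zone == "below") 1 else -1
    steps_pos <- c(steps_pos, 1 + s * d / 100)
    steps_neg <- c(steps_neg, 1 - s * d / 100)
    abnormal <- c(abnormal, nm)
  }
  seq_prod <- function(steps) {
    out <- 1
    for (f in steps) out <- max(out * f, 0)
    out
  }
  list(positive = seq_prod(steps_pos), negative = seq_prod(steps_neg),
       abnormal = abnormal)
}

#' Apply context adjustment to a rule set
#'
#' For every context variable out of its normal range, each rule's support
#' is adjusted per the four cases of [adjusted_support()] (sequentially
#' when several variables are abnormal), confidence and interest are
#' recomputed from the adjusted support (confidence capped at 1), and the
#' rules are re-tested against `ms`: rules falling below are pruned, and
#' provisional rules (mined below `ms` inside the adjustment band) whose
#' adjusted support crosses `ms` are admitted. When every variable is
#' within range the rule set is returned unchanged apart from dropping
#' provisional rules.
#'
#' @param rules A `rule_set` from [mine_rules()].
#' @param record_context Named numeric vector of the interval's context
#'   values (one value per variable; see [interval_context()]).
#' @param specs A [context_spec()] tibble covering every name in
#'   `record_context`.
#' @param th A [thresholds()] object.
#' @return The adjusted `rule_set`; modified rules carry
#'   `context_adjusted = TRUE`.
#' @export
apply_context <- function(rules, record_context, specs, th) {
  unknown <- setdiff(names(record_context), specs$name)
  if (length(unknown)) {
    abort(paste0("context value(s) with no context_spec: ",
                 paste(unknown, collapse = ", ")),
          class = "cbpnarm_error_config")
  }
  n <- attr(rules, "n_transactions")
  msf <- ms_fraction(th$ms, if (is.na(n)) Inf else n)
  fac <- context_adjustment_factors(record_context, specs)
  if (!length(fac$abnormal)) {
    out <- rules[!rules$provisional, , drop = FALSE]
    return(new_rule_set(out, n))
  }
  positive <- !rules$antecedent_negated & !rules$consequent_negated
  factor <- ifelse(positive, fac$positive, fac$negative)
  new_supp <- pmax(rules$support * factor, 0)
  new_supp <- ifelse(rules$support <= 1, pmin(new_supp, 1), new_supp)
  changed <- abs(new_supp - rules$support) > .eps
  rules$support <- new_supp
  rules$confidence <- ifelse(changed & rules$supp_antecedent > 0,
                             pmin(new_supp / rules$supp_antecedent, 1),
                             rules$confidence)
  rules$interest <- ifelse(changed,
                           abs(new_supp - rules$supp_antecedent * rules$supp_consequent),
                           rules$interest)
  rules$context_adjusted <- rules$context_adjusted | changed
  keep <- rules$support >= msf - .eps
  rules <- rules[keep, , drop = FALSE]
  rules$provisional <- FALSE
  new_rule_set(rules, n)
}
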