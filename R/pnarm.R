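#' Supports of the negated item configurations
#'
#' By inclusion-exclusion, the four signed joint events (AB, A not-B,
#' not-A B, not-A not-B) partition the sample space, so their supports
#' follow from supp(A), supp(B) and supp(AB) alone.
#'
#' @param supp_a,supp_b,supp_ab Support fractions with
#'   `0 <= supp_ab <= min(supp_a, supp_b)`.
#' @return Named numeric vector `a_notb`, `nota_b`, `nota_notb`, each in
#'   `[0, 1]`.
#' @examples
#' negative_supports(0.5, 0.4, 0.2)
#' @export
negative_supports <- function(supp_a, supp_b, supp_ab) {
  ok <- supp_a >= -.eps & supp_a <= 1 + .eps &
    supp_b >= -.eps & supp_b <= 1 + .eps &
    supp_ab >= -.eps & supp_ab <= pmin(supp_a, supp_b) + .eps &
    1 - supp_a - supp_b + supp_ab >= -.eps
  if (!all(ok)) {
    abort("inconsistent supports: need 0 <= supp_ab <= min(supp_a, supp_b) and a valid joint distribution",
          class = "cbpnarm_error_inconsistent")
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  c(a_notb = clamp01(supp_a - supp_ab),
    nota_b = clamp01(supp_b - supp_ab),
    nota_notb = clamp01(1 - supp_a - supp_b + supp_ab))
}

#' Confidence of a (possibly negated) rule
#'
#' `supp_joint / supp_antecedent`, the conditional accuracy of the rule.
#' For negated configurations the arguments are the supports of the signed
#' antecedent (e.g. `1 - supp(A)` for a not-A antecedent) and of the signed
#' joint event.
#'
#' @param supp_antecedent Support of the (signed) antecedent, > 0.
#' @param supp_joint Support of the (signed) joint event,
#'   `<= supp_antecedent`.
#' @return Confidence in `[0, 1]`.
#' @export
rule_confidence <- function(supp_antecedent, supp_joint) {
  if (any(supp_antecedent <= 0)) {
    abort("confidence undefined: antecedent support is zero",
          class = "cbpnarm_error_undefined")
  }
  if (any(supp_joint > supp_antecedent + .eps)) {
    abort("joint support exceeds antecedent support",
          class = "cbpnarm_error_inconsistent")
  }
  pmin(supp_joint / supp_antecedent, 1)
}

#' Interestingness measure
#'
#' Absolute departure of the joint support from the independence
#' expectation, `|supp(AB) - supp(A) supp(B)|`. For signed configurations
#' the complements substitute their supports; the magnitude is identical
#' for all four configurations of one (A, B) pair, and bounded by 0.25.
#'
#' @param supp_joint Support of the (signed) joint event.
#' @param supp_a,supp_b Supports of the (signed) sides.
#' @return Non-negative interest value; 0 when the sides are independent.
#' @export
interest_measure <- function(supp_joint, supp_a, supp_b) {
  abs(supp_joint - supp_a * supp_b)
}

check_disjoint <- function(a, b) {
  if (!length(a) || !length(b)) {
    abort("antecedent and consequent must be nonempty",
          class = "cbpnarm_error_contract")
  }
  if (length(intersect(a, b))) {
    abort("antecedent and consequent must be disjoint itemsets",
          class = "cbpnarm_error_contract")
  }
}

#' Frequent itemset of potential interest (positive-rule gate)
#'
#' `A => B` passes iff `supp(A u B) >= ms`, `interest(A, B) >= mi` and
#' `conf(A => B) >= mc`, with A and B disjoint nonempty itemsets.
#'
#' @param a,b Disjoint nonempty itemsets (character vectors).
#' @param supports A [frequent_itemsets()] table.
#' @param th A [thresholds()] object.
#' @return Logical.
#' @export
is_fipi <- function(a, b, supports, th) {
  check_disjoint(a, b)
  n <- attr(supports, "n_transactions")
  msf <- ms_fraction(th$ms, n)
  s_a <- st_support(supports, a)
  s_b <- st_support(supports, b)
  s_ab <- st_support(supports, union(a, b))
  if (s_a <= 0) return(FALSE)
  s_ab >= msf - .eps &&
    interest_measure(s_ab, s_a, s_b) >= th$mi - .eps &&
    s_ab / s_a >= th$mc - .eps
}

#' Infrequent itemset of potential interest (negative-rule gate)
#'
#' The signed rule passes iff both plain parts are frequent
#' (`supp(A) >= ms`, `supp(B) >= ms`), the signed joint event is frequent,
#' and the interest and confidence gates hold for the signed configuration.
#'
#' @inheritParams is_fipi
#' @param form Which negated configuration: `"A->!B"`, `"!A->B"` or
#'   `"!A->!B"`.
#' @return Logical.
#' @export
is_iipi <- function(a, b, supports, th, form = c("A->!B", "!A->B", "!A->!B")) {
  form <- match.arg(form)
  check_disjoint(a, b)
  n <- attr(supports, "n_transactions")
  msf <- ms_fraction(th$ms, n)
  s_a <- st_support(supports, a)
  s_b <- st_support(supports, b)
  if (s_a < msf - .eps || s_b < msf - .eps) return(FALSE)
  neg <- negative_supports(s_a, s_b, st_support(supports, union(a, b)))
  cfg <- switch(form,
    "A->!B" = list(joint = neg[["a_notb"]], ant = s_a, cons = 1 - s_b),
    "!A->B" = list(joint = neg[["nota_b"]], ant = 1 - s_a, cons = s_b),
    "!A->!B" = list(joint = neg[["nota_notb"]], ant = 1 - s_a, cons = 1 - s_b)
  )
  if (cfg$ant <= 0) return(FALSE)
  cfg$joint >= msf - .eps &&
    interest_measure(cfg$joint, cfg$ant, cfg$cons) >= th$mi - .eps &&
    cfg$joint / cfg$ant >= th$mc - .eps
}

#' Mine positive and negative association rules
#'
#' Enumerates every ordered pair (A, B) of disjoint frequent itemsets
#' within the size caps and emits the positive rule `A => B` when it passes
#' [is_fipi()] and the three negated forms when they pass [is_iipi()].
#' Positive rules over bipartitions of frequent itemsets and pairs of
#' disjoint frequent itemsets with frequent union coincide, by
#' anti-monotonicity. Joint supports for all pairs are obtained in one
#' cross-product over the transaction incidence matrix.
#'
#' When `ms_floor < ms` (used by context adjustment), rules whose signed
#' joint support lies in `[ms_floor, ms)` are retained and flagged
#' `provisional`; they only survive [apply_context()] if the adjustment
#' lifts them past `ms`.
#'
#' @param supports A [frequent_itemsets()] table (mined at `ms_floor` when
#'   a floor is used, otherwise at `th$ms`).
#' @param th A [thresholds()] object.
#' @param interval Origin time-interval index stamped on every rule.
#' @param max_antecedent,max_consequent Size caps for the two sides.
#' @param ms_floor Optional exploration floor below `th$ms` (fraction or
#'   count, like `ms`).
#' @return A `rule_set` tibble; one row per rule with support, confidence,
#'   interest and the signed side supports.
#' @export
mine_rules <- function(supports, th, interval = 1L,
                       max_antecedent = 4L, max_consequent = 7L,
                       ms_floor = NULL) {
  n <- attr(supports, "n_transactions")
  msf <- ms_fraction(th$ms, n)
  floor_ <- if (is.null(ms_floor)) msf else min(msf, ms_fraction(ms_floor, n))
  freq <- supports[supports$frequent, , drop = FALSE]
  nf <- nrow(freq)
  if (nf < 2) return(empty_rule_set(n_transactions = n))

  universe <- sort_items(unlist(freq$items))
  tr <- attr(supports, "transactions")
  tmat <- matrix(FALSE, n, length(universe), dimnames = list(NULL, universe))
  for (i in seq_len(n)) {
    pres <- intersect(tr[[i]], universe)
    if (length(pres)) tmat[i, pres] <- TRUE
  }
  imat <- matrix(FALSE, nf, length(universe), dimnames = list(NULL, universe))
  for (i in seq_len(nf)) imat[i, freq$items[[i]]] <- TRUE

  sizes <- freq$size
  contains <- (tmat %*% t(imat)) == matrix(sizes, n, nf, byrow = TRUE)
  joint <- crossprod(contains) / n          # supp(A u B) for every pair
  disjoint <- (imat %*% t(imat)) == 0
  s_a <- matrix(freq$support, nf, nf)       # rows: antecedent A
  s_b <- t(s_a)                             # cols: consequent B
  interest <- abs(joint - s_a * s_b)        # same magnitude for all forms

  pair_ok <- disjoint &
    outer(sizes <= max_antecedent, sizes <= max_consequent, "&")
  gate_mi <- interest >= th$mi - .eps
  both_freq <- outer(freq$support >= msf - .eps,
                     freq$support >= msf - .eps, "&")

  collect <- function(mask, joint_m, ant_m, cons_m, a_neg, b_neg) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble(
      interval = as.integer(interval),
      antecedent = freq$items[idx[, 1]],
      consequent = freq$items[idx[, 2]],
      antecedent_negated = a_neg,
      consequent_negated = b_neg,
      support = joint_m[idx],
      confidence = pmin(joint_m[idx] / ant_m[idx], 1),
      interest = interest[idx],
      supp_antecedent = ant_m[idx],
      supp_consequent = cons_m[idx],
      context_adjusted = FALSE,
      provisional = joint_m[idx] < msf - .eps
    )
  }

  cons_pos <- s_b
  pos <- pair_ok & gate_mi & s_a > 0 &
    joint >= floor_ - .eps & joint / pmax(s_a, .eps) >= th$mc - .eps

  j_anb <- pmax(s_a - joint, 0)
  j_nab <- pmax(s_b - joint, 0)
  j_nanb <- pmax(1 - s_a - s_b + joint, 0)
  neg_base <- pair_ok & gate_mi & both_freq
  neg1 <- neg_base & s_a > 0 &
    j_anb >= floor_ - .eps & j_anb / pmax(s_a, .eps) >= th$mc - .eps
  neg2 <- neg_base & (1 - s_a) > 0 &
    j_nab >= floor_ - .eps & j_nab / pmax(1 - s_a, .eps) >= th$mc - .eps
  neg3 <- neg_base & (1 - s_a) > 0 &
    j_nanb >= floor_ - .eps & j_nanb / pmax(1 - s_a, .eps) >= th$mc - .eps

  out <- bind_rows(
    collect(pos, joint, s_a, cons_pos, FALSE, FALSE),
    collect(neg1, j_anb, s_a, 1 - s_b, FALSE, TRUE),
    collect(neg2, j_nab, 1 - s_a, s_b, TRUE, FALSE),
    collect(neg3, j_nanb, 1 - s_a, 1 - s_b, TRUE, TRUE)
  )
  if (is.null(out) || !nrow(out)) return(empty_rule_set(n_transactions = n))
  out <- out[!duplicated(rule_keys(out)), , drop = FALSE]
  new_rule_set(out, n_transactions = n)
}
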