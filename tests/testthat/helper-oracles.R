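# Independent brute-force oracles for the mining core. These enumerate the
# full powerset / all signed itemset pairs with bitmask arithmetic and never
# touch the package's levelwise machinery, so agreement is a real check.

# all nonempty subsets of the item universe with exact supports, as a list
# indexed by bitmask value
bf_enumerate <- function(transactions) {
  items <- sort(unique(unlist(transactions)), method = "radix")
  p <- length(items)
  stopifnot(p <= 12)
  n <- length(transactions)
  tmask <- vapply(transactions, function(t) {
    sum(2^(match(unique(t[t %in% items]), items) - 1))
  }, 0)
  masks <- seq_len(2^p - 1)
  supp <- vapply(masks, function(m) mean(bitwAnd(tmask, m) == m), 0)
  sizes <- vapply(masks, function(m) {
    sum(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
  }, 0)
  list(items = items, p = p, n = n, masks = masks, supp = supp, sizes = sizes)
}

mask_items <- function(mask, items) {
  items[bitwAnd(mask, 2^(seq_along(items) - 1)) > 0]
}

# frequent itemsets by exhaustive counting: tibble(key, support)
bf_frequent <- function(transactions, ms) {
  e <- bf_enumerate(transactions)
  msf <- if (ms > 1) ms / e$n else ms
  keep <- e$supp >= msf - 1e-12
  tibble::tibble(
    key = vapply(e$masks[keep], function(m) {
      cbpnarm::itemset_key(mask_items(m, e$items))
    }, ""),
    support = e$supp[keep]
  )
}

# every positive and negative rule over all disjoint signed pairs, by direct
# arithmetic on the enumerated supports: tibble(key, support)
bf_rules <- function(transactions, th, max_ant = Inf, max_cons = Inf) {
  e <- bf_enumerate(transactions)
  msf <- if (th$ms > 1) th$ms / e$n else th$ms
  nm <- length(e$masks)
  supp_ext <- c(e$supp, rep(NA_real_, 2^e$p))
  D <- outer(e$masks, e$masks, bitwAnd) == 0
  U <- outer(e$masks, e$masks, "+")
  SAB <- matrix(supp_ext[ifelse(D, U, 1L)], nm, nm)
  SA <- matrix(e$supp, nm, nm)
  SB <- t(SA)
  size_ok <- outer(e$sizes <= max_ant, e$sizes <= max_cons, "&")
  interest <- abs(SAB - SA * SB)
  gate <- D & size_ok & interest >= th$mi - 1e-12
  rows <- list()
  emit <- function(mask, joint, a_neg, b_neg) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      key = vapply(seq_len(nrow(idx)), function(r) {
        paste0(if (a_neg) "!{" else "{",
               cbpnarm::itemset_key(mask_items(e$masks[idx[r, 1]], e$items)),
               "} => ",
               if (b_neg) "!{" else "{",
               cbpnarm::itemset_key(mask_items(e$masks[idx[r, 2]], e$items)),
               "}")
      }, ""),
      support = joint[idx]
    )
  }
  pos <- gate & SAB >= msf - 1e-12 & SA > 0 & SAB / SA >= th$mc - 1e-12
  emit(pos, SAB, FALSE, FALSE)
  both <- gate & SA >= msf - 1e-12 & SB >= msf - 1e-12
  j1 <- SA - SAB
  emit(both & j1 >= msf - 1e-12 & SA > 0 & j1 / SA >= th$mc - 1e-12,
       j1, FALSE, TRUE)
  j2 <- SB - SAB
  emit(both & j2 >= msf - 1e-12 & (1 - SA) > 0 & j2 / (1 - SA) >= th$mc - 1e-12,
       j2, TRUE, FALSE)
  j3 <- 1 - SA - SB + SAB
  emit(both & j3 >= msf - 1e-12 & (1 - SA) > 0 & j3 / (1 - SA) >= th$mc - 1e-12,
       j3, TRUE, TRUE)
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(key = character(), support = double())
  }
}

# small random transaction database over items A..H
random_transactions <- function(n_items = 5, n_transactions = 12,
                                p_item = 0.5) {
  items <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n_transactions), function(i) {
    items[stats::runif(n_items) < p_item]
  })
}

# tiny in-memory database for data-model tests: 2 sites x 2 dates
tiny_db_csv <- function(path) {
  df <- tibble::tibble(
    prospect_id = c("P1", "P2", "P3", "P4"),
    site = c("S1", "S1", "S2", "S2"),
    date_of_evaluation = as.Date(c("2004-01-01", "2004-02-01",
                                   "2004-01-01", "2004-02-01")),
    coordinates = "33 43 00N 73 04 00E",
    prospect = c(TRUE, TRUE, FALSE, FALSE),
    context_rainfall = c(250, 250, 450, 120),
    context_temperature = c(20, 25, 30, 22),
    Nmob = c(340, 0, 12, 0),
    Apd = c(0, 5, 7, 0),
    Pheh = c(1.2, 0, 3.4, 0)
  )
  readr::write_csv(df, path)
  path
}

demo_rule1_key <- function() {
  rule_key(c("is_a(Apd,>=X1)", "is_a(Pheh,>=X2)", "diff_of(Aio.Rps,>X3)",
             "color_of(soil,Y1)"),
           "found(MP,true)")
}

demo_rule2_key <- function() {
  rule_key(c("is_a(Apd,>=X1)", "is_a(Pheh,>=X2)", "diff_of(Aio.Rps,>X3)",
             "color_of(soil,Y1)", "is_a(Ni,>=X3)"),
           "found(MP,true)")
}
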