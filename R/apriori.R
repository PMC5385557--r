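#' Support of an itemset
#'
#' @param itemset Character vector of item tokens (the empty itemset has
#'   support 1 by the vacuous-subset convention).
#' @param transactions Nonempty list of itemsets.
#' @return A list with `count` (transactions containing the itemset) and
#'   `support` (`count / length(transactions)`).
#' @examples
#' tr <- list(c("A", "B"), c("A", "B"), c("A", "C"))
#' itemset_support(c("A", "B"), tr)
#' @export
itemset_support <- function(itemset, transactions) {
  if (!length(transactions)) {
    abort("support undefined on an empty transaction list",
          class = "cbpnarm_error_contract")
  }
  itemset <- unique(as.character(itemset))
  count <- sum(vapply(transactions, function(t) all(itemset %in% t), TRUE))
  list(count = as.integer(count), support = count / length(transactions))
}

#' Apriori candidate generation (join + prune)
#'
#' Joins pairs of size-k frequent itemsets sharing a (k-1)-prefix and
#' prunes any candidate with an infrequent k-subset, exploiting support
#' anti-monotonicity.
#'
#' @param frequent_k List of size-k frequent itemsets (character vectors).
#' @return Duplicate-free list of size-(k+1) candidates in canonical order.
#' @export
generate_candidates <- function(frequent_k) {
  if (!length(frequent_k)) return(list())
  sets <- lapply(frequent_k, sort_items)
  sizes <- lengths(sets)
  if (length(unique(sizes)) != 1) {
    abort("all frequent itemsets passed to candidate generation must share one size",
          class = "cbpnarm_error_contract")
  }
  k <- sizes[[1]]
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets <- sets[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  prefixes <- vapply(sets, function(s) paste(s[seq_len(k - 1)], collapse = "\r"), "")
  cands <- list()
  for (grp in split(sets, prefixes)) {
    if (length(grp) < 2) next
    last <- vapply(grp, function(s) s[k], "")
    grp <- grp[order(last, method = "radix")]
    last <- sort(last, method = "radix")
    for (i in seq_len(length(grp) - 1)) {
      for (j in (i + 1):length(grp)) {
        cands[[length(cands) + 1]] <- c(grp[[i]], last[j])
      }
    }
  }
  if (!length(cands)) return(list())
  keep <- vapply(cands, function(cand) {
    subs <- vapply(seq_len(k + 1), function(d) paste(cand[-d], collapse = "\r"), "")
    all(subs %in% keys)
  }, TRUE)
  cands[keep]
}

#' Levelwise frequent-itemset mining
#'
#' Classical Apriori over one interval's transactions. All singleton
#' supports are retained in the table even below `ms` (flagged
#' `frequent = FALSE`) because negative-rule generation needs marginal
#' supports; they never enter candidate generation. The transaction list
#' is kept as an attribute so joint supports of itemset pairs can be
#' computed on demand during rule mining.
#'
#' @param transactions Nonempty list of itemsets.
#' @param ms Minimum support: a fraction in (0, 1], or an absolute count
#'   (> 1) divided by the number of transactions.
#' @return A `support_table` tibble with columns `key`, `items`
#'   (list-column), `size`, `support`, `count`, `frequent`, and attributes
#'   `n_transactions`, `ms` (as a fraction) and `transactions`.
#' @examples
#' tr <- list(c("A", "B"), c("A", "B"), c("A", "C"))
#' frequent_itemsets(tr, ms = 2/3)
#' @export
frequent_itemsets <- function(transactions, ms) {
  n <- length(transactions)
  if (!n) abort("cannot mine an empty transaction list",
                class = "cbpnarm_error_contract")
  msf <- ms_fraction(ms, n)
  if (msf <= 0) abort("ms must be positive", class = "cbpnarm_error_config")
  universe <- sort_items(unlist(transactions))
  rows <- list()
  if (length(universe)) {
    mat <- matrix(FALSE, n, length(universe),
                  dimnames = list(NULL, universe))
    for (i in seq_len(n)) mat[i, transactions[[i]]] <- TRUE
    counts1 <- unname(colSums(mat))
    rows[[1]] <- tibble(
      key = universe,
      items = as.list(universe),
      size = 1L,
      support = counts1 / n,
      count = as.integer(counts1),
      frequent = counts1 / n >= msf - .eps
    )
    current <- rows[[1]]$items[rows[[1]]$frequent]
    k <- 1L
    while (length(current) >= 2) {
      cands <- generate_candidates(current)
      if (!length(cands)) break
      k <- k + 1L
      counts <- vapply(cands, function(s) {
        sum(rowSums(mat[, s, drop = FALSE]) == length(s))
      }, 0)
      keep <- counts / n >= msf - .eps
      if (!any(keep)) break
      cands <- cands[keep]
      counts <- counts[keep]
      rows[[k]] <- tibble(
        key = vapply(cands, itemset_key, ""),
        items = cands,
        size = k,
        support = counts / n,
        count = as.integer(counts),
        frequent = TRUE
      )
      current <- cands
    }
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(key = character(), items = list(), size = integer(),
           support = double(), count = integer(), frequent = logical())
  }
  attr(out, "n_transactions") <- n
  attr(out, "ms") <- msf
  attr(out, "transactions") <- transactions
  class(out) <- unique(c("support_table", class(out)))
  out
}

#' @export
print.support_table <- function(x, ...) {
  cat(sprintf("<support_table> %d itemsets (%d frequent at ms = %.4g) over %d transactions\n",
              nrow(x), sum(x$frequent), attr(x, "ms"), attr(x, "n_transactions")))
  NextMethod()
}

# support lookup with fallback to on-demand counting from the retained
# transaction list (needed for joint supports below ms)
st_support <- function(supports, items) {
  i <- match(itemset_key(items), supports$key)
  if (!is.na(i)) return(supports$support[i])
  itemset_support(items, attr(supports, "transactions"))$support
}
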