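#' Indicator range table for ordinal discretization
#'
#' Per-indicator breakpoints and ordinal labels. Bins are half-open
#' `[b_i, b_{i+1})`: a value exactly at a breakpoint belongs to the upper
#' bin. Breakpoints are user-supplied domain knowledge (indicator value
#' ranges are survey-specific and not shipped with the package).
#'
#' @param indicator Indicator id.
#' @param breaks Strictly increasing numeric breakpoints (length m >= 2).
#' @param labels Ordinal labels, one per bin (length m - 1), unique within
#'   the indicator.
#' @return A one-row tibble with list-columns `breaks` and `labels`;
#'   combine rows with [dplyr::bind_rows()].
#' @examples
#' range_table("Nmob", c(0, 10, 100, 1000), c("low", "med", "high"))
#' @export
range_table <- function(indicator, breaks, labels) {
  breaks <- as.numeric(breaks)
  labels <- as.character(labels)
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    abort("breakpoints must be strictly increasing, length >= 2",
          class = "cbpnarm_error_config")
  }
  if (length(labels) != length(breaks) - 1 || anyDuplicated(labels)) {
    abort("need one unique label per bin", class = "cbpnarm_error_config")
  }
  tibble(indicator = indicator, breaks = list(breaks), labels = list(labels))
}

#' Map a raw indicator value to an ordinal item
#'
#' @param value Numeric raw measurement(s).
#' @param indicator Indicator id, present in `ranges`.
#' @param ranges A [range_table()] tibble.
#' @param policy `"clamp"` maps out-of-range values to the edge bins;
#'   `"strict"` raises an out-of-range error.
#' @return Character vector of item tokens, one per value; the relation
#'   field records the bin predicate, e.g. `"in[0,10)"`.
#' @examples
#' rt <- range_table("Nmob", c(0, 10, 100), c("low", "high"))
#' ordinalize(5, "Nmob", rt)
#' ordinalize(10, "Nmob", rt)  # breakpoint goes to the upper bin
#' @export
ordinalize <- function(value, indicator, ranges, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  row <- which(ranges$indicator == indicator)
  if (!length(row)) {
    abort(sprintf("no range defined for indicator '%s'", indicator),
          class = "cbpnarm_error_config")
  }
  breaks <- ranges$breaks[[row[1]]]
  labels <- ranges$labels[[row[1]]]
  idx <- findInterval(value, breaks)  # half-open [b_i, b_{i+1})
  out_low <- idx < 1
  out_high <- idx > length(labels)
  if (policy == "strict" && any(out_low | out_high)) {
    abort(sprintf("value %g out of range for indicator '%s'",
                  value[which(out_low | out_high)[1]], indicator),
          class = "cbpnarm_error_range")
  }
  idx <- pmin(pmax(idx, 1L), length(labels))
  rel <- sprintf("in[%g,%g)", breaks[idx], breaks[idx + 1])
  item(rep(indicator, length(value)), labels[idx], rel)
}

#' Binarize indicator presence
#'
#' Implements the presence view used for mining: every indicator with a
#' strictly positive raw value becomes a presence item (`<id> == 1`); zero,
#' negative or missing values yield no item (absence is not treated as
#' evidence, which matters for negative rules). A true prospect outcome
#' becomes the item `MP == 1`. The operation recomputes the `items` column
#' from the raw indicator columns, so it is idempotent and conserves the
#' record count.
#'
#' @param db A `prospect_db` with raw indicator columns.
#' @return The same database with an `items` list-column.
#' @export
binarize_presence <- function(db) {
  inds <- attr(db, "indicators")
  mat <- as.matrix(as_tibble(db)[inds])
  present <- !is.na(mat) & mat > 0
  db$items <- lapply(seq_len(nrow(db)), function(i) {
    it <- presence_item(inds[present[i, ]])
    if (isTRUE(db$prospect[i])) it <- c(it, prospect_item())
    sort_items(it)
  })
  db
}

#' Ordinalize a whole database
#'
#' Maps each non-missing indicator value through [ordinalize()]; missing
#' values yield no item. The prospect outcome becomes `MP == 1` when true.
#'
#' @inheritParams binarize_presence
#' @param ranges A [range_table()] tibble covering every indicator to be
#'   discretized; indicators without a range are skipped.
#' @param policy Passed to [ordinalize()].
#' @return The database with an `items` list-column.
#' @export
ordinalize_database <- function(db, ranges, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  inds <- intersect(attr(db, "indicators"), ranges$indicator)
  tokens <- matrix(NA_character_, nrow(db), length(inds))
  for (j in seq_along(inds)) {
    v <- db[[inds[j]]]
    ok <- !is.na(v)
    if (any(ok)) {
      tokens[ok, j] <- ordinalize(v[ok], inds[j], ranges, policy)
    }
  }
  db$items <- lapply(seq_len(nrow(db)), function(i) {
    it <- tokens[i, !is.na(tokens[i, ])]
    if (isTRUE(db$prospect[i])) it <- c(it, prospect_item())
    sort_items(it)
  })
  db
}

#' Transactions of one time interval
#'
#' @param db A discretized `prospect_db` (run [binarize_presence()] or
#'   [ordinalize_database()] first).
#' @param interval Time-interval index.
#' @return List of itemsets (character vectors), one per record of the
#'   interval, in record order.
#' @export
build_transactions <- function(db, interval) {
  if (!"items" %in% names(db)) {
    abort("database is not discretized; run binarize_presence() or ordinalize_database() first",
          class = "cbpnarm_error_contract")
  }
  keep <- db$interval == interval
  if (!any(keep)) {
    abort(sprintf("interval %s not present in database", format(interval)),
          class = "cbpnarm_error_lookup")
  }
  db$items[keep]
}
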