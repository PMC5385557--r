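#' Context variable specification
#'
#' A context variable is an external environmental measurement (rainfall,
#' temperature, ...) whose abnormal value can falsely generate or suppress
#' association rules. Its normal range is `[civ, cfv]` (context initial /
#' final value), chosen by the domain expert; values outside trigger support
#' adjustment (see [adjusted_support()]).
#'
#' @param name Variable name(s); must be unique within a database.
#' @param civ,cfv Lower / upper bound of the normal range, in the
#'   variable's own units; `civ < cfv` elementwise.
#' @return A tibble with columns `name`, `civ`, `cfv`.
#' @examples
#' context_spec("rainfall", 100, 300)
#' @export
context_spec <- function(name, civ, cfv) {
  name <- as.character(name)
  civ <- as.numeric(civ)
  cfv <- as.numeric(cfv)
  if (any(duplicated(name))) {
    abort("context variable names must be unique", class = "cbpnarm_error_config")
  }
  if (any(!is.finite(civ)) || any(!is.finite(cfv)) || any(civ >= cfv)) {
    abort("context range requires finite civ < cfv", class = "cbpnarm_error_config")
  }
  tibble(name = name, civ = civ, cfv = cfv)
}

#' Default context specification for microbial prospection
#'
#' The five context variables carried by a microbial prospection database,
#' with field-plausible normal ranges: air temperature 15-40 degC, water
#' salinity 1-35 g/L, relative humidity 30-80 %, monthly rainfall
#' 100-300 mm, fossil pollution 1-10 ppm.
#'
#' @return A tibble of five [context_spec()] rows.
#' @export
default_context_specs <- function() {
  context_spec(
    name = c("temperature", "salinity", "humidity", "rainfall", "fossil"),
    civ = c(15, 1, 30, 100, 1),
    cfv = c(40, 35, 80, 300, 10)
  )
}

#' Mining thresholds
#'
#' @param ms Minimum support. A value in (0, 1] is a fraction of the
#'   interval's transactions; a value > 1 is an absolute transaction count,
#'   converted per interval by dividing by that interval's record count.
#' @param mc Minimum confidence in `[0, 1]`.
#' @param mi Minimum interest in `[0, 1]`; the interestingness gate prunes
#'   rules whose joint support is explainable by independence.
#' @param k Temporal intersection threshold: a rule must be extracted at
#'   `>= k` distinct time intervals to enter the final rule set.
#' @return A list of class `"thresholds"`.
#' @examples
#' thresholds(ms = 3, mc = 0.7, mi = 0.05, k = 3)
#' @export
thresholds <- function(ms = 0.3, mc = 0.7, mi = 0.05, k = 3) {
  if (!is.numeric(ms) || length(ms) != 1 || ms <= 0) {
    abort("ms must be a positive number", class = "cbpnarm_error_config")
  }
  if (!is.numeric(mc) || mc < 0 || mc > 1) {
    abort("mc must lie in [0, 1]", class = "cbpnarm_error_config")
  }
  if (!is.numeric(mi) || mi < 0 || mi > 1) {
    abort("mi must lie in [0, 1]", class = "cbpnarm_error_config")
  }
  if (!is.numeric(k) || k < 1) {
    abort("k must be >= 1", class = "cbpnarm_error_config")
  }
  structure(list(ms = ms, mc = mc, mi = mi, k = as.integer(k)),
            class = "thresholds")
}

# ms as a fraction of n transactions (counts > 1 are divided by n)
ms_fraction <- function(ms, n) {
  if (ms > 1) ms / n else ms
}

new_prospect_db <- function(tbl, context_specs, indicators) {
  out <- as_tibble(tbl)
  attr(out, "context_specs") <- context_specs
  attr(out, "indicators") <- indicators
  class(out) <- c("prospect_db", class(out))
  out
}

#' @export
print.prospect_db <- function(x, ...) {
  specs <- attr(x, "context_specs")
  cat(sprintf(
    "<prospect_db> %d records, %d sites, %d intervals, %d indicators, %d context variables\n",
    nrow(x), length(unique(x$site)), length(unique(x$interval)),
    length(attr(x, "indicators")), if (is.null(specs)) 0L else nrow(specs)
  ))
  NextMethod()
}

context_col <- function(name) paste0("context_", name)

#' Read a microbial prospection database from CSV
#'
#' Expects one row per (site, sampling date): identifier columns
#' `prospect_id`, `site`, `date_of_evaluation`, a logical/0-1 `prospect`
#' outcome, context measurements in columns named `context_<name>`, and one
#' numeric raw-value column per indicator. Time-interval indices are
#' assigned per site by sorting that site's distinct evaluation dates, so a
#' database round-trips through [write_database()] unchanged.
#'
#' @param path CSV file (UTF-8, header row).
#' @param context_specs A [context_spec()] tibble; every listed variable
#'   must have a matching `context_<name>` column. Defaults to the
#'   variables found in the file, with ranges from
#'   [default_context_specs()] where the names match.
#' @param indicators Indicator column names; defaults to every numeric
#'   column not otherwise recognised.
#' @return A `prospect_db` tibble with an `interval` column added.
#' @export
load_database <- function(path, context_specs = NULL, indicators = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("prospect_id", "site", "date_of_evaluation", "prospect")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    abort(paste0("schema error: missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cbpnarm_error_schema")
  }
  raw$prospect_id <- as.character(raw$prospect_id)
  raw$site <- as.character(raw$site)
  ctx_cols <- grep("^context_", names(raw), value = TRUE)
  if (is.null(context_specs)) {
    found <- sub("^context_", "", ctx_cols)
    defaults <- default_context_specs()
    context_specs <- defaults[defaults$name %in% found, ]
    extra <- setdiff(found, defaults$name)
    if (length(extra)) {
      # unknown variables get a degenerate placeholder range the caller
      # should override; flagged by validate_database()
      context_specs <- bind_rows(context_specs,
                                 context_spec(extra, 0, 1e6))
    }
  }
  need <- context_col(context_specs$name)
  miss_ctx <- setdiff(need, names(raw))
  if (length(miss_ctx)) {
    abort(paste0("schema error: context column(s) missing: ",
                 paste(miss_ctx, collapse = ", ")),
          class = "cbpnarm_error_schema")
  }
  for (cc in need) {
    v <- raw[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad)) {
        abort(sprintf("parse error: non-numeric context value in column %s at row %d",
                      cc, bad[1]),
              class = "cbpnarm_error_parse")
      }
      raw[[cc]] <- vn
    }
  }
  if (!inherits(raw$date_of_evaluation, "Date")) {
    raw$date_of_evaluation <- as.Date(raw$date_of_evaluation)
  }
  raw$prospect <- as.logical(raw$prospect)
  if (is.null(indicators)) {
    known <- c(mandatory, "coordinates", need, "interval")
    indicators <- setdiff(names(raw), known)
    indicators <- indicators[vapply(raw[indicators], is.numeric, TRUE)]
  }
  if (anyDuplicated(raw[c("site", "date_of_evaluation")])) {
    abort("integrity error: duplicate (site, date_of_evaluation) record",
          class = "cbpnarm_error_integrity")
  }
  db <- raw |>
    group_by(site) |>
    mutate(interval = match(date_of_evaluation,
                            sort(unique(date_of_evaluation)))) |>
    ungroup() |>
    arrange(site, interval, prospect_id) |>
    relocate(interval, .after = site)
  new_prospect_db(db, context_specs, indicators)
}

#' Write a prospection database to CSV
#'
#' Drops derived columns (`interval`, `items`) so that
#' `load_database(write_database(db))` reproduces `db` field-wise.
#'
#' @param db A `prospect_db`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  out <- as_tibble(db)
  out$interval <- NULL
  out$items <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a prospection database
#'
#' Checks the structural invariants mining relies on and reports findings
#' instead of failing: an empty report means the database is mineable.
#'
#' @param db A `prospect_db`.
#' @return A tibble with columns `type` and `message`; zero rows when the
#'   database is well-formed.
#' @export
validate_database <- function(db) {
  findings <- list()
  say <- function(type, msg) {
    findings[[length(findings) + 1]] <<- tibble(type = type, message = msg)
  }
  if (nrow(db) < 1) say("empty", "database holds no records")
  dup <- duplicated(db[c("site", "interval")])
  if (any(dup)) {
    d <- db[dup, , drop = FALSE]
    say("duplicate_site_interval",
        sprintf("site %s interval %d appears more than once",
                d$site[1], d$interval[1]))
  }
  if (any(db$interval < 1)) say("bad_interval", "interval indices must be >= 1")
  specs <- attr(db, "context_specs")
  ctx_cols <- grep("^context_", names(db), value = TRUE)
  unknown <- setdiff(sub("^context_", "", ctx_cols),
                     if (is.null(specs)) character() else specs$name)
  for (u in unknown) {
    say("unknown_context",
        sprintf("context values present for '%s' but no context_spec declares it", u))
  }
  if (!is.null(specs)) {
    for (i in seq_len(nrow(specs))) {
      cc <- context_col(specs$name[i])
      if (cc %in% names(db) && anyNA(db[[cc]])) {
        say("missing_context", sprintf("NA context values in %s", cc))
      }
    }
  }
  if ("items" %in% names(db)) {
    dup_items <- map_lgl(db$items, function(x) anyDuplicated(x) > 0)
    if (any(dup_items)) say("duplicate_items", "a record's itemset contains duplicates")
  }
  if (length(findings)) bind_rows(findings) else tibble(type = character(),
                                                        message = character())
}

new_rule_set <- function(tbl, n_transactions = NA_integer_) {
  out <- as_tibble(tbl)
  attr(out, "n_transactions") <- n_transactions
  class(out) <- unique(c("rule_set", class(out)))
  out
}

empty_rule_set <- function(interval = integer(), n_transactions = NA_integer_) {
  new_rule_set(tibble(
    interval = integer(),
    antecedent = list(),
    consequent = list(),
    antecedent_negated = logical(),
    consequent_negated = logical(),
    support = double(),
    confidence = double(),
    interest = double(),
    supp_antecedent = double(),
    supp_consequent = double(),
    context_adjusted = logical(),
    provisional = logical()
  ), n_transactions)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules (%d positive, %d negative)\n",
              nrow(x),
              sum(!x$antecedent_negated & !x$consequent_negated),
              sum(x$antecedent_negated | x$consequent_negated)))
  NextMethod()
}

# human-readable side of a rule, e.g. "!{A == 1 & B == 1}"
side_string <- function(items, negated) {
  paste0(ifelse(negated, "!{", "{"),
         map_chr(items, itemset_key), "}")
}

#' Serialize association rules to CSV
#'
#' One row per rule with canonical antecedent and consequent strings,
#' polarity flags, support, confidence, interest, origin interval and the
#' context-adjusted flag. Rules sharing an antecedent are written as
#' adjacent rows (each antecedent listed against all of its consequents);
#' antecedent groups are ordered by descending best support, then best
#' confidence, then the canonical antecedent string, and rows within a
#' group by descending support and confidence. Consequents are limited to
#' 7 items.
#'
#' @param rules A `rule_set` (or final rule set) tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  if (nrow(rules) > 0 && any(lengths(rules$consequent) > 7)) {
    abort("serialization error: rule consequent exceeds 7 items",
          class = "cbpnarm_error_serialize")
  }
  flat <- tidy_rules(rules)
  if (!nrow(flat)) {
    readr::write_csv(flat, path, progress = FALSE)
    return(invisible(path))
  }
  flat <- flat |>
    group_by(.ant_key = paste0(antecedent, "|", antecedent_negated)) |>
    mutate(.grp_supp = max(support), .grp_conf = max(confidence)) |>
    ungroup() |>
    arrange(desc(.grp_supp), desc(.grp_conf), antecedent,
            desc(support), desc(confidence), consequent) |>
    select(-.ant_key, -.grp_supp, -.grp_conf)
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

# flatten list-columns to canonical strings (shared by write_rules and tidy);
# consolidated rule sets carry interval_count + contributing intervals instead
# of a single origin interval
tidy_rules <- function(rules) {
  out <- tibble(
    antecedent = map_chr(rules$antecedent, itemset_key),
    consequent = map_chr(rules$consequent, itemset_key),
    antecedent_negated = rules$antecedent_negated,
    consequent_negated = rules$consequent_negated,
    support = rules$support,
    confidence = rules$confidence,
    interest = rules$interest,
    context_adjusted = rules$context_adjusted
  )
  if ("interval_count" %in% names(rules)) {
    out$interval_count <- rules$interval_count
    out$intervals <- map_chr(rules$intervals, paste, collapse = ";")
  } else {
    out$interval <- rules$interval
  }
  out
}

#' Read association rules written by [write_rules()]
#'
#' @param path CSV path.
#' @return A `rule_set` tibble with list-column antecedents/consequents.
#' @export
read_rules <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("antecedent", "consequent", "antecedent_negated",
            "consequent_negated", "support", "confidence", "interest",
            "interval", "context_adjusted")
  missing <- setdiff(need, names(flat))
  if (length(missing)) {
    abort(paste0("rule file missing column(s): ", paste(missing, collapse = ", ")),
          class = "cbpnarm_error_schema")
  }
  new_rule_set(tibble(
    interval = as.integer(flat$interval),
    antecedent = strsplit(flat$antecedent, " & ", fixed = TRUE),
    consequent = strsplit(flat$consequent, " & ", fixed = TRUE),
    antecedent_negated = as.logical(flat$antecedent_negated),
    consequent_negated = as.logical(flat$consequent_negated),
    support = as.numeric(flat$support),
    confidence = as.numeric(flat$confidence),
    interest = as.numeric(flat$interest),
    supp_antecedent = NA_real_,
    supp_consequent = NA_real_,
    context_adjusted = as.logical(flat$context_adjusted),
    provisional = FALSE
  ))
}

#' Read a mining configuration file
#'
#' YAML with optional blocks: `thresholds` (ms, mc, mi, k),
#' `context_specs` (list of name/civ/cfv), `ranges` (per-indicator
#' breakpoints and labels for ordinal discretization), `mode`
#' ("binary"/"ordinal"), `context` (true/false).
#'
#' @param path YAML file.
#' @return A list with elements `thresholds`, `context_specs`, `ranges`,
#'   `mode`, `context` (missing blocks are `NULL` or defaults).
#' @export
read_mining_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- if (!is.null(cfg$thresholds)) do.call(thresholds, cfg$thresholds) else thresholds()
  specs <- if (!is.null(cfg$context_specs)) {
    bind_rows(lapply(cfg$context_specs, function(s) {
      context_spec(s$name, s$civ, s$cfv)
    }))
  }
  ranges <- if (!is.null(cfg$ranges)) {
    bind_rows(lapply(cfg$ranges, function(r) {
      range_table(r$indicator, as.numeric(r$breaks), as.character(r$labels))
    }))
  }
  list(
    thresholds = th,
    context_specs = specs,
    ranges = ranges,
    mode = cfg$mode %||% "binary",
    context = cfg$context %||% TRUE
  )
}
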