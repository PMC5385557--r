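#' Per-interval context values
#'
#' The context value used for an interval's rule set is the median of the
#' interval's per-record values (one value per variable). Disagreement
#' between records is reported when `options(cbpnarm.verbose = TRUE)`.
#'
#' @param db A `prospect_db`.
#' @param interval Interval index.
#' @param specs A [context_spec()] tibble.
#' @return Named numeric vector of context values.
#' @export
interval_context <- function(db, interval, specs) {
  rows <- db$interval == interval
  out <- vapply(specs$name, function(nm) {
    cc <- context_col(nm)
    if (!cc %in% names(db)) return(NA_real_)
    v <- db[[cc]][rows]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    if (length(unique(v)) > 1 && isTRUE(getOption("cbpnarm.verbose"))) {
      inform(sprintf("interval %d: records disagree on context '%s'; using the median",
                     interval, nm))
    }
    median(v)
  }, 0)
  setNames(out, specs$name)
}

#' Mine a prospection database end to end
#'
#' Orchestrates discretization, per-interval Apriori and rule mining,
#' optional context-based support adjustment, and temporal consolidation.
#' With context on, each interval whose (median) context is out of range
#' is mined down to the exploration floor `ms / max(1, F)` (F the
#' polarity-wise adjustment factor) so that rules promotable past `ms` by
#' the adjustment are available; [apply_context()] then adjusts, re-tests
#' and prunes.
#'
#' @param db A `prospect_db`.
#' @param th A [thresholds()] object.
#' @param context Apply context adjustment? (`TRUE`/`FALSE`.)
#' @param specs Context specs; default those attached to `db`, possibly
#'   subset to enable only some variables.
#' @param mode `"binary"` (presence items) or `"ordinal"` (requires
#'   `ranges`).
#' @param ranges A [range_table()] tibble for ordinal mode.
#' @param max_antecedent,max_consequent Rule side size caps.
#' @return A `cbpnarm_run` list: `final` (consolidated rules), `rulesets`
#'   (per-interval rule sets), `report` (one-row count summary),
#'   `thresholds`, `context`.
#' @export
mine_database <- function(db, th, context = TRUE,
                          specs = attr(db, "context_specs"),
                          mode = c("binary", "ordinal"), ranges = NULL,
                          max_antecedent = 4L, max_consequent = 7L) {
  mode <- match.arg(mode)
  db2 <- if (mode == "binary") {
    binarize_presence(db)
  } else {
    if (is.null(ranges)) {
      abort("ordinal mode needs a range table", class = "cbpnarm_error_config")
    }
    ordinalize_database(db, ranges)
  }
  if (context && (is.null(specs) || !nrow(specs))) {
    abort("context adjustment requested but no context specs available",
          class = "cbpnarm_error_config")
  }
  ivs <- sort(unique(db2$interval))
  n_frequent <- 0L
  rulesets <- lapply(ivs, function(iv) {
    tr <- build_transactions(db2, iv)
    msf <- ms_fraction(th$ms, length(tr))
    floor_ <- msf
    ctx <- NULL
    if (context) {
      ctx <- interval_context(db2, iv, specs)
      fac <- context_adjustment_factors(ctx[!is.na(ctx)], specs)
      floor_ <- msf / max(1, fac$positive, fac$negative)
    }
    st <- frequent_itemsets(tr, floor_)
    n_frequent <<- n_frequent + sum(st$frequent)
    rs <- mine_rules(st, th, iv, max_antecedent, max_consequent,
                     ms_floor = floor_)
    if (context) rs <- apply_context(rs, ctx[!is.na(ctx)], specs, th)
    rs
  })
  final <- intersect_rulesets(rulesets, th$k)
  all_rules <- bind_rows(lapply(rulesets, as_tibble))
  report <- tibble(
    n_records = nrow(db), n_intervals = length(ivs),
    n_frequent_itemsets = n_frequent,
    n_rules = nrow(all_rules),
    n_positive = sum(!all_rules$antecedent_negated & !all_rules$consequent_negated),
    n_negative = sum(all_rules$antecedent_negated | all_rules$consequent_negated),
    n_adjusted = sum(all_rules$context_adjusted),
    n_final = nrow(final),
    ms = th$ms, mc = th$mc, mi = th$mi, k = th$k,
    context = context
  )
  structure(list(final = final, rulesets = rulesets, report = report,
                 thresholds = th, context = context),
            class = "cbpnarm_run")
}

#' @export
print.cbpnarm_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "<cbpnarm_run> %d records over %d intervals (context %s)\n",
    "  rules: %d positive + %d negative (%d context-adjusted)\n",
    "  final rule set (k = %d): %d rules\n"),
    r$n_records, r$n_intervals, if (x$context) "on" else "off",
    r$n_positive, r$n_negative, r$n_adjusted, r$k, r$n_final))
  invisible(x)
}

#' Compare mining regimes across a minimum-support grid
#'
#' Runs the pipeline with context adjustment off, on for all variables,
#' and on for a subset, across a grid of `ms` values, reporting rule
#' counts and mean confidence per regime - the comparison used to show
#' that abnormal context prunes rules.
#'
#' @param db A `prospect_db`.
#' @param th Base [thresholds()]; `ms` is replaced by each grid value.
#' @param ms_grid Numeric vector of minimum supports.
#' @param subset Variable names for the `"subset"` regime (default: first
#'   half of the specs).
#' @param ... Passed to [mine_database()].
#' @return A `cbpnarm_compare` tibble: `regime`, `ms`, `n_rules`,
#'   `n_positive`, `n_negative`, `mean_confidence`, `n_final`.
#' @export
compare_modes <- function(db, th, ms_grid = seq(0.2, 0.6, by = 0.1),
                          subset = NULL, ...) {
  specs <- attr(db, "context_specs")
  if (is.null(subset)) subset <- specs$name[seq_len(ceiling(nrow(specs) / 2))]
  regimes <- list(
    off = list(context = FALSE, specs = specs),
    on = list(context = TRUE, specs = specs),
    subset = list(context = TRUE, specs = specs[specs$name %in% subset, ])
  )
  rows <- list()
  for (rg in names(regimes)) {
    for (m in ms_grid) {
      th_m <- thresholds(ms = m, mc = th$mc, mi = th$mi, k = th$k)
      run <- mine_database(db, th_m, context = regimes[[rg]]$context,
                           specs = regimes[[rg]]$specs, ...)
      all_rules <- bind_rows(lapply(run$rulesets, as_tibble))
      rows[[length(rows) + 1]] <- tibble(
        regime = rg, ms = m,
        n_rules = nrow(all_rules),
        n_positive = run$report$n_positive,
        n_negative = run$report$n_negative,
        mean_confidence = if (nrow(all_rules)) mean(all_rules$confidence) else NA_real_,
        n_final = run$report$n_final
      )
    }
  }
  out <- bind_rows(rows)
  class(out) <- unique(c("cbpnarm_compare", class(out)))
  out
}

#' Run the full pipeline from files
#'
#' Thin orchestration for the command line: load a database CSV and a
#' mining config, mine, and write the artifacts (final rules, per-interval
#' rules, run report) into an output directory.
#'
#' @param input Database CSV path.
#' @param out_dir Output directory (created if missing).
#' @param config Optional YAML config path (see [read_mining_config()]).
#' @param th,context,mode Overrides for the corresponding config values.
#' @return The `cbpnarm_run`, invisibly.
#' @export
run_pipeline <- function(input, out_dir, config = NULL, th = NULL,
                         context = NULL, mode = NULL) {
  cfg <- if (!is.null(config)) read_mining_config(config) else {
    list(thresholds = thresholds(), context_specs = NULL, ranges = NULL,
         mode = "binary", context = TRUE)
  }
  th <- th %||% cfg$thresholds
  context <- context %||% cfg$context
  mode <- mode %||% cfg$mode
  if (!file.exists(input)) {
    abort(sprintf("data error: input file '%s' not found", input),
          class = "cbpnarm_error_data")
  }
  db <- load_database(input, context_specs = cfg$context_specs)
  issues <- validate_database(db)
  if (nrow(issues)) {
    abort(paste0("data error: ", paste(issues$message, collapse = "; ")),
          class = "cbpnarm_error_data")
  }
  run <- mine_database(db, th, context = context, mode = mode,
                       ranges = cfg$ranges)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_rules(run$final, file.path(out_dir, "final_rules.csv"))
  per_interval <- bind_rows(lapply(run$rulesets, as_tibble))
  write_rules(new_rule_set(per_interval),
              file.path(out_dir, "interval_rules.csv"))
  readr::write_csv(run$report, file.path(out_dir, "run_report.csv"),
                   progress = FALSE)
  invisible(run)
}
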