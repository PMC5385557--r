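#' Configuration for the synthetic database generator
#'
#' Defaults reproduce the benchmark shape of the motivating survey: 28
#' sites sampled over 178 time intervals (4984 records), the 29 microbial
#' indicators, 20 of 28 sites holding energy, and 7 abnormal-context
#' records per context variable.
#'
#' Planted rules are indicator sets tied to the prospect outcome with
#' target joint support `s` and confidence `c`. Planting is by exact
#' counts: in each interval of n records, `round(s * n)` prospect-site
#' records receive the full antecedent, and `round(s n (1 - c) / c)`
#' non-prospect records receive it without the outcome, so empirical
#' support and confidence match the targets up to rounding and background
#' noise. Feasibility requires `s <= prospect_fraction`,
#' `s (1 - c) / c <= 1 - prospect_fraction`, and `s <= c`.
#'
#' @param n_sites,n_intervals Database shape; one record per (site,
#'   interval).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param indicators Indicator catalogue (default the 29 standard
#'   abbreviations).
#' @param planted_rules List of lists with elements `antecedent`
#'   (indicator ids), `support`, `confidence`, and optionally
#'   `interval_support` (length-`n_intervals` per-interval support
#'   override).
#' @param context_specs Normal ranges for the context variables.
#' @param n_abnormal Out-of-range context records injected per variable.
#' @param abnormal_side `"above"` or `"below"`.
#' @param prospect_fraction Fraction of sites with energy.
#' @param background_rate Marginal presence probability of each indicator
#'   outside planting.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_sites = 28L, n_intervals = 178L, seed = 1L,
                             indicators = microbial_indicators,
                             planted_rules = list(
                               list(antecedent = c("Apd", "Pheh", "Aio"),
                                    support = 0.3, confidence = 0.9),
                               list(antecedent = c("Nmob", "Neob"),
                                    support = 0.35, confidence = 0.85)
                             ),
                             context_specs = default_context_specs(),
                             n_abnormal = 7L,
                             abnormal_side = c("above", "below"),
                             prospect_fraction = 20 / 28,
                             background_rate = 0.15) {
  abnormal_side <- match.arg(abnormal_side)
  if (prospect_fraction <= 0 || prospect_fraction >= 1) {
    abort("prospect_fraction must lie strictly between 0 and 1",
          class = "cbpnarm_error_config")
  }
  for (r in planted_rules) {
    if (!all(r$antecedent %in% indicators)) {
      abort("planted antecedent uses an unknown indicator",
            class = "cbpnarm_error_config")
    }
    s_all <- c(r$support, r$interval_support)
    if (any(s_all > r$confidence + .eps) ||
        any(s_all > prospect_fraction + .eps) ||
        any(s_all * (1 - r$confidence) / r$confidence >
            1 - prospect_fraction + .eps)) {
      abort("infeasible planted-rule targets for the given prospect_fraction",
            class = "cbpnarm_error_config")
    }
    if (!is.null(r$interval_support) &&
        length(r$interval_support) != n_intervals) {
      abort("interval_support must have one value per interval",
            class = "cbpnarm_error_config")
    }
  }
  structure(list(
    n_sites = as.integer(n_sites), n_intervals = as.integer(n_intervals),
    seed = as.integer(seed), indicators = indicators,
    planted_rules = planted_rules, context_specs = context_specs,
    n_abnormal = as.integer(n_abnormal), abnormal_side = abnormal_side,
    prospect_fraction = prospect_fraction, background_rate = background_rate
  ), class = "generator_config")
}

# a positive raw measurement for a presence cell
raw_value <- function(n) round(runif(n, 10, 500), 1)

#' Generate a synthetic microbial prospection database
#'
#' Draws background indicator presence independently per cell at the
#' configured marginal rate, plants the configured rules by exact counts
#' (see [generator_config()]), samples context values uniformly within
#' their normal ranges, and injects the configured number of out-of-range
#' context records per variable (uniform on the adjacent band of one range
#' width). Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return A `prospect_db` tibble of `n_sites * n_intervals` records with
#'   raw indicator values, context columns and the prospect flag.
#' @export
generate_database <- function(config) {
  withr::with_seed(config$seed, {
    n_sites <- config$n_sites
    n_int <- config$n_intervals
    sites <- sprintf("S%02d", seq_len(n_sites))
    n_pros <- round(config$prospect_fraction * n_sites)
    prospect_sites <- sample(sites, n_pros)
    grid <- tidyr::expand_grid(site = sites, interval = seq_len(n_int)) |>
      arrange(site, interval)
    n_rec <- nrow(grid)
    db <- tibble(
      prospect_id = sprintf("P%05d", seq_len(n_rec)),
      site = grid$site,
      interval = grid$interval,
      date_of_evaluation = as.Date("2004-03-01") + 28L * (grid$interval - 1L),
      coordinates = "33 43 00N 73 04 00E",
      prospect = grid$site %in% prospect_sites
    )
    p <- length(config$indicators)
    present <- matrix(rbinom(n_rec * p, 1L, config$background_rate) == 1L,
                      n_rec, p, dimnames = list(NULL, config$indicators))
    vals <- matrix(0, n_rec, p, dimnames = list(NULL, config$indicators))
    vals[present] <- raw_value(sum(present))
    for (rule in config$planted_rules) {
      for (iv in seq_len(n_int)) {
        s_iv <- if (!is.null(rule$interval_support)) {
          rule$interval_support[iv]
        } else {
          rule$support
        }
        rows_iv <- which(db$interval == iv)
        pros <- rows_iv[db$prospect[rows_iv]]
        nonpros <- setdiff(rows_iv, pros)
        n_ab <- round(s_iv * length(rows_iv))
        n_a <- round(n_ab * (1 - rule$confidence) / rule$confidence)
        pick_ab <- pros[sample.int(length(pros), min(n_ab, length(pros)))]
        pick_a <- nonpros[sample.int(length(nonpros), min(n_a, length(nonpros)))]
        for (ind in rule$antecedent) {
          rows <- c(pick_ab, pick_a)
          zero <- rows[vals[rows, ind] <= 0]
          if (length(zero)) vals[zero, ind] <- raw_value(length(zero))
        }
      }
    }
    for (j in seq_len(nrow(config$context_specs))) {
      sp <- config$context_specs[j, ]
      v <- runif(n_rec, sp$civ, sp$cfv)
      if (config$n_abnormal > 0) {
        width <- sp$cfv - sp$civ
        idx <- sample(n_rec, min(config$n_abnormal, n_rec))
        v[idx] <- if (config$abnormal_side == "above") {
          runif(length(idx), sp$cfv + 1e-6 * width, sp$cfv + width)
        } else {
          runif(length(idx), max(sp$civ - width, 1e-6 * width),
                sp$civ - 1e-6 * width)
        }
      }
      db[[context_col(sp$name)]] <- round(v, 2)
    }
    db <- bind_cols(db, as_tibble(vals))
    new_prospect_db(db, config$context_specs, config$indicators)
  })
}

#' Inject a context anomaly
#'
#' Sets the chosen records' context value outside the normal range by a
#' stated multiple of the range width, leaving every other field
#' untouched. Used to construct the abnormal-context scenarios the
#' adjustment step is designed to correct.
#'
#' @param db A `prospect_db`.
#' @param variable Context variable name (must be in the database's
#'   context specs).
#' @param records Integer row indices to modify, or `NULL` to use
#'   `intervals`.
#' @param intervals Interval indices whose records are all modified
#'   (ignored when `records` is given).
#' @param magnitude Multiple of the range width beyond the violated bound;
#'   `0` places the value exactly at the bound (still within range, with a
#'   warning).
#' @param side `"above"` (beyond CFV) or `"below"` (beyond CIV).
#' @return The modified database.
#' @export
inject_context_anomaly <- function(db, variable, records = NULL,
                                   intervals = NULL, magnitude = 0.75,
                                   side = c("above", "below")) {
  side <- match.arg(side)
  specs <- attr(db, "context_specs")
  sp <- specs[specs$name == variable, ]
  if (!nrow(sp)) {
    abort(sprintf("no context_spec for variable '%s'", variable),
          class = "cbpnarm_error_config")
  }
  if (is.null(records)) {
    if (is.null(intervals)) {
      abort("give either records or intervals", class = "cbpnarm_error_contract")
    }
    records <- which(db$interval %in% intervals)
  }
  if (any(records < 1 | records > nrow(db))) {
    abort("record selector out of bounds", class = "cbpnarm_error_index")
  }
  width <- sp$cfv - sp$civ
  if (magnitude == 0) {
    warn("magnitude 0 places the value exactly at the range boundary (still within range)")
  }
  value <- if (side == "above") sp$cfv + magnitude * width
           else sp$civ - magnitude * width
  db[[context_col(variable)]][records] <- value
  db
}

#' Planted-rule manifest
#'
#' Machine-readable list of the planted rule keys and targets, for
#' recovery scoring: each planted rule's key is what the full pipeline
#' should deliver in its final rule set.
#'
#' @param config A [generator_config()].
#' @return Tibble with `key`, `antecedent` (list of item tokens),
#'   `consequent`, `support`, `confidence`.
#' @export
truth_table <- function(config) {
  if (!length(config$planted_rules)) {
    return(tibble(key = character(), antecedent = list(),
                  consequent = character(), support = double(),
                  confidence = double()))
  }
  rows <- lapply(config$planted_rules, function(r) {
    ant <- presence_item(r$antecedent)
    tibble(
      key = rule_key(ant, prospect_item()),
      antecedent = list(sort_items(ant)),
      consequent = prospect_item(),
      support = r$support,
      confidence = r$confidence
    )
  })
  bind_rows(rows)
}

#' Suppression-and-rescue demonstration scenario
#'
#' Builds the motivating abnormal-context scenario end to end: one rule
#' ({Apd, Pheh, Aio} => MP) planted over five sampling intervals, strongly
#' supported at intervals 1-2, suppressed into the adjustment band (below
#' the minimum support) at intervals 3-4 where rainfall is driven below
#' its normal range (50 mm against a 100-300 mm range, a 100 % deficit,
#' so the adjustment doubles the observed support), and genuinely weak at
#' interval 5. Mining with context off extracts the rule at only 2
#' intervals, so consolidation at `k = 3` drops it; with context on, the
#' adjustment restores the two suppressed intervals and the rule enters
#' the final set.
#'
#' @param seed Integer seed for the generator.
#' @return A list: `db` (the database), `thresholds` (ms 0.4, mc 0.5,
#'   mi 0.005, k 3), `key` (the planted rule's [rule_key()]),
#'   `anomalous_intervals` (3 and 4).
#' @export
rescue_scenario <- function(seed = 1L) {
  config <- generator_config(
    n_sites = 28L, n_intervals = 5L, seed = seed,
    planted_rules = list(list(
      antecedent = c("Apd", "Pheh", "Aio"),
      support = 0.5, confidence = 0.85,
      interval_support = c(0.5, 0.5, 0.32, 0.32, 0.1)
    )),
    n_abnormal = 0L
  )
  db <- generate_database(config)
  db <- inject_context_anomaly(db, "rainfall", intervals = c(3L, 4L),
                               magnitude = 0.25, side = "below")
  list(
    db = db,
    thresholds = thresholds(ms = 0.4, mc = 0.5, mi = 0.005, k = 3),
    key = truth_table(config)$key,
    anomalous_intervals = c(3L, 4L)
  )
}
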