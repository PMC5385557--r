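test_that("loading assigns per-site intervals and round-trips through write", {
  csv <- tiny_db_csv(withr::local_tempfile(fileext = ".csv"))
  db <- load_database(csv)
  expect_s3_class(db, "prospect_db")
  expect_equal(nrow(db), 4)
  expect_equal(sort(unique(db$interval)), c(1L, 2L))
  expect_setequal(attr(db, "indicators"), c("Nmob", "Apd", "Pheh"))
  expect_equal(nrow(validate_database(db)), 0)

  out <- withr::local_tempfile(fileext = ".csv")
  write_database(db, out)
  db2 <- load_database(out)
  expect_equal(as.data.frame(db2), as.data.frame(db))

  # row order within the file must not matter
  shuffled <- readr::read_csv(csv, show_col_types = FALSE)[c(3, 1, 4, 2), ]
  sh <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, sh)
  expect_equal(as.data.frame(load_database(sh)), as.data.frame(db))
})

test_that("schema and integrity violations are reported by name", {
  csv <- tiny_db_csv(withr::local_tempfile(fileext = ".csv"))
  raw <- readr::read_csv(csv, show_col_types = FALSE)

  no_site <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw[setdiff(names(raw), "site")], no_site)
  expect_error(load_database(no_site), "site", class = "cbpnarm_error_schema")

  no_rain <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw[setdiff(names(raw), "context_rainfall")], no_rain)
  expect_error(load_database(no_rain, context_specs = default_context_specs()[4, ]),
               "context_rainfall", class = "cbpnarm_error_schema")

  dup <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rbind(raw, raw[1, ]), dup)
  expect_error(load_database(dup), class = "cbpnarm_error_integrity")

  bad_ctx <- raw
  bad_ctx$context_rainfall <- as.character(bad_ctx$context_rainfall)
  bad_ctx$context_rainfall[3] <- "heavy"
  bc <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad_ctx, bc)
  expect_error(load_database(bc), "row 3", class = "cbpnarm_error_parse")
})

test_that("validate_database reports duplicates and unknown context variables", {
  csv <- tiny_db_csv(withr::local_tempfile(fileext = ".csv"))
  db <- load_database(csv)

  dup <- db
  dup$interval[2] <- 1L
  rep <- validate_database(dup)
  expect_true("duplicate_site_interval" %in% rep$type)

  orphan <- db
  attr(orphan, "context_specs") <- default_context_specs()[4, ]  # rainfall only
  rep2 <- validate_database(orphan)
  expect_true("unknown_context" %in% rep2$type)
})

test_that("rule serialization round-trips and groups antecedents", {
  rules <- new_rule_set_for_test <- structure(tibble::tibble(
    interval = c(1L, 1L, 1L),
    antecedent = list(c("B == 1", "A == 1"), c("A == 1", "B == 1"), "C == 1"),
    consequent = list("MP == 1", "D == 1", "MP == 1"),
    antecedent_negated = c(FALSE, FALSE, TRUE),
    consequent_negated = c(FALSE, TRUE, FALSE),
    support = c(0.5, 0.25, 0.4),
    confidence = c(0.9, 0.5, 0.8),
    interest = c(0.1, 0.05, 0.2),
    supp_antecedent = NA_real_,
    supp_consequent = NA_real_,
    context_adjusted = FALSE,
    provisional = FALSE
  ), class = c("rule_set", class(tibble::tibble())))

  path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, path)
  flat <- readr::read_csv(path, show_col_types = FALSE)
  # the two rules sharing antecedent {A, B} sit on adjacent rows
  shared <- which(flat$antecedent == "A == 1 & B == 1")
  expect_equal(diff(shared), 1)

  back <- read_rules(path)
  expect_setequal(rule_keys(back), rule_keys(rules))
  expect_equal(sort(back$support), sort(rules$support))
  expect_equal(sort(back$confidence), sort(rules$confidence))

  # empty rule collection gives a header-only file
  empty_path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules[0, ], empty_path)
  expect_equal(nrow(readr::read_csv(empty_path, show_col_types = FALSE)), 0)

  # over-long consequents are refused
  wide <- rules[1, ]
  wide$consequent <- list(paste0(LETTERS[1:8], " == 1"))
  expect_error(write_rules(wide, path), class = "cbpnarm_error_serialize")
})

test_that("item tokens and itemset keys are canonical and stable", {
  expect_equal(item("Apd", 1), "Apd == 1")
  expect_equal(itemset_key(c("B == 1", "A == 1", "B == 1")),
               itemset_key(c("A == 1", "B == 1")))
  expect_equal(itemset_key(character()), "")
})

test_that("thresholds and context specs validate their domains", {
  expect_s3_class(thresholds(ms = 3, mc = 0.7, mi = 0.05, k = 3), "thresholds")
  expect_error(thresholds(ms = 0), class = "cbpnarm_error_config")
  expect_error(thresholds(mc = 1.2), class = "cbpnarm_error_config")
  expect_error(thresholds(k = 0), class = "cbpnarm_error_config")
  expect_error(context_spec("rainfall", 300, 100), class = "cbpnarm_error_config")
  expect_error(context_spec(c("a", "a"), c(0, 0), c(1, 1)),
               class = "cbpnarm_error_config")
})
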