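rain <- context_spec("rainfall", 100, 300)

test_that("context classification is inclusive at the range bounds", {
  expect_equal(classify_context(250, rain), "within")
  expect_equal(classify_context(450, rain), "above")
  expect_equal(classify_context(50, rain), "below")
  expect_equal(classify_context(c(100, 300), rain), c("within", "within"))
})

test_that("the four adjustment cases follow the surplus formulas", {
  # above-range, positive rule: 450 vs [100, 300] -> 33.3 % cut
  a <- adjusted_support(5, 450, rain, "positive")
  expect_equal(a$difference, (450 - 300) * 100 / 450)
  expect_equal(a$new_support, 5 - 5 * a$difference / 100, tolerance = 1e-12)
  expect_equal(a$new_support, 10 / 3, tolerance = 1e-9)
  expect_equal(a$case_id, "positive-above")

  # within range: identity for either polarity
  expect_equal(adjusted_support(5, 250, rain, "positive")$new_support, 5)
  expect_equal(adjusted_support(5, 250, rain, "negative")$new_support, 5)
  expect_equal(adjusted_support(5, 250, rain, "negative")$difference, 0)

  # below-range, negative rule: 100 % deficit clamps to zero
  b <- adjusted_support(4, 50, rain, "negative")
  expect_equal(b$difference, 100)
  expect_equal(b$new_support, 0)

  # below-range, positive rule gains; above-range, negative rule gains
  expect_equal(adjusted_support(4, 50, rain, "positive")$new_support, 8)
  expect_equal(adjusted_support(0.5, 450, rain, "negative")$new_support,
               0.5 + 0.5 * (150 * 100 / 450) / 100)

  # fractional supports are clamped into [0, 1]
  expect_equal(adjusted_support(0.9, 50, rain, "positive")$new_support, 1)
  expect_error(adjusted_support(5, 0, rain, "positive"),
               class = "cbpnarm_error_adjustment")
  expect_error(adjusted_support(-1, 250, rain, "positive"),
               class = "cbpnarm_error_contract")
})

test_that("adjustment magnitude grows with distance from the violated bound", {
  grid_above <- seq(310, 800, by = 10)
  new_above <- vapply(grid_above, function(v) {
    adjusted_support(5, v, rain, "positive")$new_support
  }, 0)
  expect_true(all(diff(new_above) < 0))  # farther above -> bigger cut
  grid_below <- seq(95, 10, by = -5)
  new_below <- vapply(grid_below, function(v) {
    adjusted_support(5, v, rain, "positive")$new_support
  }, 0)
  expect_true(all(diff(new_below) > 0))  # farther below -> bigger boost
})

test_that("sign correctness: polarity and zone fix the direction of change", {
  withr::with_seed(77, {
    for (i in 1:100) {
      v <- runif(1, 10, 600)
      s <- runif(1, 0.05, 0.9)
      zone <- classify_context(v, rain)
      pos <- adjusted_support(s, v, rain, "positive")$new_support
      neg <- adjusted_support(s, v, rain, "negative")$new_support
      expect_gte(pos, 0); expect_gte(neg, 0)
      expect_lte(pos, 1); expect_lte(neg, 1)
      if (zone == "above") {
        expect_lte(pos, s + 1e-12)
        expect_gte(neg, s - 1e-12)
      } else if (zone == "below") {
        expect_gte(pos, s - 1e-12)
        expect_lte(neg, s + 1e-12)
      } else {
        expect_equal(pos, s); expect_equal(neg, s)
      }
    }
  })
})

make_rules <- function(supports, supp_ant = 0.8, supp_cons = 0.7) {
  n <- length(supports)
  structure(tibble::tibble(
    interval = 1L,
    antecedent = lapply(seq_len(n), function(i) paste0("A", i, " == 1")),
    consequent = rep(list("MP == 1"), n),
    antecedent_negated = FALSE,
    consequent_negated = FALSE,
    support = supports,
    confidence = supports / supp_ant,
    interest = abs(supports - supp_ant * supp_cons),
    supp_antecedent = supp_ant,
    supp_consequent = supp_cons,
    context_adjusted = FALSE,
    provisional = FALSE
  ), class = c("rule_set", class(tibble::tibble())),
  n_transactions = 100L)
}

specs2 <- context_spec(c("rainfall", "temperature"), c(100, 15), c(300, 40))

test_that("apply_context is the identity when every variable is in range", {
  rules <- make_rules(c(0.5, 0.35))
  out <- apply_context(rules, c(rainfall = 250, temperature = 20), specs2,
                       thresholds(ms = 0.3, mc = 0, mi = 0, k = 1))
  expect_equal(as.data.frame(out), as.data.frame(rules))
  expect_false(any(out$context_adjusted))
})

test_that("above-range context prunes a positive rule sitting just above ms", {
  th <- thresholds(ms = 0.4, mc = 0, mi = 0, k = 1)
  rules <- make_rules(c(0.42, 0.8))  # 0.42 = ms * 1.05
  # 20 % above cfv: value v with (v - 300)/v = 0.2 -> v = 375
  out <- apply_context(rules, c(rainfall = 375), specs2, th)
  expect_equal(nrow(out), 1)
  expect_equal(out$support, 0.8 * 0.8)
  expect_true(out$context_adjusted)
  # confidence and interest were recomputed from the adjusted support
  expect_equal(out$confidence, 0.64 / 0.8)
  expect_equal(out$interest, abs(0.64 - 0.8 * 0.7))
})

test_that("multiple abnormal variables compose multiplicatively", {
  th <- thresholds(ms = 0.05, mc = 0, mi = 0, k = 1)
  rules <- make_rules(0.5)
  # rainfall 20 % above (factor 0.8), temperature 50 vs cfv 40 (factor 0.8)
  out <- apply_context(rules, c(rainfall = 375, temperature = 50), specs2, th)
  expect_equal(out$support, 0.5 * 0.8 * 0.8, tolerance = 1e-12)
  # order of the specs does not matter
  out2 <- apply_context(rules, c(temperature = 50, rainfall = 375),
                        specs2[2:1, ], th)
  expect_equal(out2$support, out$support)
})

test_that("unknown context names are rejected", {
  rules <- make_rules(0.5)
  expect_error(
    apply_context(rules, c(salinity = 40), specs2, thresholds()),
    class = "cbpnarm_error_config"
  )
})
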