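test_that("negated configuration supports follow inclusion-exclusion", {
  expect_equal(negative_supports(0.5, 0.4, 0.2),
               c(a_notb = 0.3, nota_b = 0.2, nota_notb = 0.3))
  # empirical containment A in B: A never occurs without B
  expect_equal(negative_supports(0.3, 0.6, 0.3)[["a_notb"]], 0)
  expect_error(negative_supports(0.2, 0.2, 0.3),
               class = "cbpnarm_error_inconsistent")
  # the four signed supports partition unity
  withr::with_seed(11, {
    for (i in 1:50) {
      sa <- runif(1)
      sb <- runif(1)
      sab <- runif(1, max(0, sa + sb - 1), min(sa, sb))
      neg <- negative_supports(sa, sb, sab)
      expect_equal(sab + sum(neg), 1, tolerance = 1e-12)
    }
  })
})

test_that("confidence is conditional accuracy and rejects bad inputs", {
  expect_equal(rule_confidence(0.5, 0.4), 0.8)
  expect_equal(rule_confidence(0.5, 0.5), 1)
  expect_error(rule_confidence(0, 0), class = "cbpnarm_error_undefined")
  expect_error(rule_confidence(0.3, 0.4), class = "cbpnarm_error_inconsistent")
  # against brute-force conditional frequency
  withr::with_seed(3, {
    tr <- random_transactions(n_items = 4, n_transactions = 20)
    sa <- itemset_support("A", tr)$support
    sab <- itemset_support(c("A", "B"), tr)$support
    if (sa > 0) {
      direct <- mean(vapply(tr[vapply(tr, function(t) "A" %in% t, TRUE)],
                            function(t) "B" %in% t, TRUE))
      expect_equal(rule_confidence(sa, sab), direct, tolerance = 1e-12)
    }
  })
})

test_that("the fipi gate applies support, interest and confidence jointly", {
  # supports arranged directly: A in 3/5, B in 3/5, AB in 2.5/5 is not
  # constructible; use a concrete database realizing the 0.5/0.6/0.6 case
  tr <- c(rep(list(c("A", "B")), 5), rep(list("A"), 1), rep(list("B"), 1),
          rep(list(c("A", "C")), 0), rep(list("Z"), 3))
  # supp(A) = 0.6, supp(B) = 0.6, supp(AB) = 0.5
  st <- frequent_itemsets(tr, 0.3)
  th <- thresholds(ms = 0.3, mc = 0.7, mi = 0.05, k = 1)
  expect_true(is_fipi("A", "B", st, th))   # interest 0.14, conf 0.833
  expect_error(is_fipi(c("A", "B"), "B", st, th),
               class = "cbpnarm_error_contract")

  # independent items fail any positive interest gate
  tr_ind <- c(rep(list(c("A", "B")), 1), rep(list("A"), 1),
              rep(list("B"), 1), rep(list("Z"), 1))
  st_ind <- frequent_itemsets(tr_ind, 0.2)
  expect_false(is_fipi("A", "B", st_ind, thresholds(ms = 0.2, mc = 0, mi = 0.01)))
})

test_that("the iipi gate admits the A -> not-B form on anti-correlated items", {
  # n = 10: 1 AB, 5 A-only, 4 B-only -> supp(A) = 0.6, supp(B) = 0.5,
  # supp(AB) = 0.1
  tr <- c(rep(list(c("A", "B")), 1), rep(list("A"), 5), rep(list("B"), 4))
  st <- frequent_itemsets(tr, 0.3)
  th <- thresholds(ms = 0.3, mc = 0.7, mi = 0.05, k = 1)
  # supp(A u !B) = 0.5, interest = |0.5 - 0.6 * 0.5| = 0.2, conf = 0.833
  expect_true(is_iipi("A", "B", st, th, form = "A->!B"))
  # an infrequent side blocks every form regardless of the joint
  th_hi <- thresholds(ms = 0.55, mc = 0, mi = 0, k = 1)
  expect_false(is_iipi("A", "B", st, th_hi, form = "A->!B"))
})

test_that("perfectly co-occurring items yield both directed rules at conf 1", {
  tr <- c(rep(list(c("A", "B")), 3), rep(list("Z"), 3))
  st <- frequent_itemsets(tr, 0.5)
  rs <- mine_rules(st, thresholds(ms = 0.5, mc = 0.5, mi = 0, k = 1))
  keys <- rule_keys(rs)
  expect_true(rule_key("A", "B") %in% keys)
  expect_true(rule_key("B", "A") %in% keys)
  expect_equal(rs$confidence[match(rule_key("A", "B"), keys)], 1)
})

test_that("mined rules match brute-force signed-pair enumeration", {
  withr::with_seed(202, {
    for (rep in 1:40) {
      tr <- random_transactions(n_items = sample(3:6, 1),
                                n_transactions = sample(6:20, 1),
                                p_item = runif(1, 0.3, 0.7))
      if (!length(unlist(tr))) next
      th <- thresholds(ms = runif(1, 0.15, 0.45), mc = runif(1, 0.3, 0.8),
                       mi = runif(1, 0, 0.1), k = 1)
      st <- frequent_itemsets(tr, th$ms)
      got <- mine_rules(st, th, max_antecedent = 6, max_consequent = 6)
      want <- bf_rules(tr, th, max_ant = 6, max_cons = 6)
      got_keys <- rule_keys(got)
      expect_setequal(got_keys, want$key)
      expect_equal(got$support[match(want$key, got_keys)], want$support,
                   tolerance = 1e-12)
    }
  })
})

test_that("with mi = mc = 0 the positive side reduces to plain Apriori rules", {
  withr::with_seed(5, {
    tr <- random_transactions(n_items = 5, n_transactions = 15)
    th <- thresholds(ms = 0.25, mc = 0, mi = 0, k = 1)
    st <- frequent_itemsets(tr, th$ms)
    rs <- mine_rules(st, th, max_antecedent = 5, max_consequent = 5)
    pos <- rs[!rs$antecedent_negated & !rs$consequent_negated, ]
    # plain Apriori rule set: every bipartition of every frequent itemset
    want <- list()
    for (i in which(st$frequent & st$size >= 2)) {
      z <- st$items[[i]]
      for (m in 1:(2^length(z) - 2)) {
        a <- z[bitwAnd(m, 2^(seq_along(z) - 1)) > 0]
        want[[length(want) + 1]] <- rule_key(a, setdiff(z, a))
      }
    }
    expect_setequal(rule_keys(pos), unique(unlist(want)))
  })
})

test_that("raising ms never adds a rule", {
  withr::with_seed(9, {
    tr <- random_transactions(n_items = 6, n_transactions = 18)
    th_lo <- thresholds(ms = 0.2, mc = 0.5, mi = 0.01, k = 1)
    keys_prev <- NULL
    for (ms in c(0.2, 0.3, 0.4, 0.5)) {
      th <- thresholds(ms = ms, mc = th_lo$mc, mi = th_lo$mi, k = 1)
      keys <- rule_keys(mine_rules(frequent_itemsets(tr, ms), th))
      if (!is.null(keys_prev)) expect_true(all(keys %in% keys_prev))
      keys_prev <- keys
    }
  })
})

test_that("interest is symmetric, bounded by 0.25, and shared across forms", {
  withr::with_seed(13, {
    for (i in 1:100) {
      sa <- runif(1)
      sb <- runif(1)
      sab <- runif(1, max(0, sa + sb - 1), min(sa, sb))
      i_pos <- interest_measure(sab, sa, sb)
      expect_equal(i_pos, interest_measure(sab, sb, sa))
      expect_lte(i_pos, 0.25 + 1e-12)
      neg <- negative_supports(sa, sb, sab)
      expect_equal(interest_measure(neg[["a_notb"]], sa, 1 - sb), i_pos,
                   tolerance = 1e-12)
      expect_equal(interest_measure(neg[["nota_notb"]], 1 - sa, 1 - sb), i_pos,
                   tolerance = 1e-12)
    }
  })
})
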