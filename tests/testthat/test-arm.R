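test_that("frequent itemsets on the textbook four-transaction example", {
  X <- matrix(c(1, 1, 0,   # AB
                1, 1, 0,   # AB
                1, 0, 1,   # AC
                0, 1, 0),  # B
              nrow = 4, byrow = TRUE, dimnames = list(NULL, c("A01", "B18", "C18")))
  sets <- apriori(X, min_support = 0.5)
  keys <- vapply(sets$items, itemset_key, "")
  expect_setequal(keys, c("A01", "B18", "A01|B18"))
  expect_equal(sets$support[match("A01", keys)], 0.75)
  expect_equal(sets$support[match("B18", keys)], 0.75)
  expect_equal(sets$support[match("A01|B18", keys)], 0.5)
})

test_that("min_support 1 keeps only ubiquitous items", {
  set.seed(3)
  X <- rand_incidence(20, 5, p = 0.6)
  X[, 2] <- 1L
  sets <- apriori(X, min_support = 1)
  expect_true(all(vapply(sets$items, function(s)
    all(colMeans(X[, s, drop = FALSE]) == 1), TRUE)))
})

test_that("apriori equals exhaustive enumeration on random matrices", {
  set.seed(8)
  for (i in 1:10) {
    X <- rand_incidence(30, 8, p = runif(1, 0.2, 0.6))
    ms <- sample(c(0.05, 0.1, 0.2), 1)
    got <- apriori(X, min_support = ms)
    want <- enumerate_itemsets(X, ms)
    got_keys <- vapply(got$items, itemset_key, "")
    want_keys <- vapply(want, function(s) itemset_key(s$items), "")
    expect_setequal(got_keys, want_keys)
    expect_equal(got$support[order(got_keys)],
                 vapply(want, `[[`, 0, "support")[order(want_keys)])
  }
})

test_that("downward closure holds for every mined itemset", {
  set.seed(15)
  X <- rand_incidence(40, 7, p = 0.4)
  sets <- apriori(X, min_support = 0.1)
  keys <- vapply(sets$items, itemset_key, "")
  for (s in sets$items[lengths(sets$items) > 1]) {
    for (drop in seq_along(s))
      expect_true(itemset_key(s[-drop]) %in% keys)
  }
})

test_that("rule metrics satisfy their defining identities", {
  m <- rule_metrics(antecedent_support = 0.09, support = 0.085,
                    consequent_support = 0.7751)
  expect_equal(m$confidence, 0.085 / 0.09)
  expect_equal(m$lift, m$confidence / 0.7751)
  expect_equal(m$leverage, 0.085 - 0.09 * 0.7751)
  expect_equal(m$conviction, (1 - 0.7751) / (1 - m$confidence))
  # confidence 1 => infinite conviction sentinel
  expect_equal(rule_metrics(0.1, 0.1, 0.5)$conviction, Inf)
})

test_that("targeted rules match direct computation and sort by lift", {
  set.seed(21)
  X <- rand_incidence(60, 6, p = 0.5,
                      codes = c("I50", "E11", "E78", "G47", "I10", "N18"))
  rules <- mine_rules(X, consequent = "I50", min_support = 0.05,
                      min_confidence = 0.3, max_antecedent = 5L)
  cons_supp <- mean(X[, "I50"])
  for (r in seq_len(nrow(rules))) {
    ante <- rules$antecedent[[r]]
    ante_supp <- mean(rowSums(X[, ante, drop = FALSE]) == length(ante))
    joint <- mean(rowSums(X[, c(ante, "I50"), drop = FALSE]) == length(ante) + 1)
    expect_equal(rules$antecedent_support[r], ante_supp)
    expect_equal(rules$support[r], joint)
    expect_equal(rules$confidence[r], joint / ante_supp)
    expect_equal(rules$lift[r], joint / ante_supp / cons_supp)
    expect_true(joint > 0.05 && joint / ante_supp > 0.3)
    # rule support never exceeds either marginal
    expect_lte(rules$support[r], min(ante_supp, cons_supp))
  }
  expect_true(all(diff(rules$lift) <= 1e-12))
})

test_that("lift, leverage, and conviction agree in sign for mined rules", {
  set.seed(27)
  X <- rand_incidence(80, 6, p = 0.5,
                      codes = c("I50", "E11", "E78", "G47", "I10", "N18"))
  rules <- mine_rules(X, consequent = "I50", min_support = 0.02,
                      min_confidence = 0.1)
  finite <- rules$confidence < 1
  expect_true(all((rules$lift > 1) == (rules$leverage > 0)))
  expect_true(all((rules$lift[finite] > 1) == (rules$conviction[finite] > 1)))
})

test_that("an absent consequent yields an empty rule set with a warning", {
  set.seed(33)
  X <- rand_incidence(30, 4, p = 0.5)
  expect_warning(rules <- mine_rules(X, consequent = "I50"), "absent")
  expect_equal(nrow(rules), 0L)
})
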