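test_that("candidate enumeration counts and order are deterministic", {
  labels <- make_labels(matrix(0L, nrow = 3, ncol = 4),
    gene_ids = c("gA", "gB", "gC")
  )
  single <- enumerate_candidates(labels, c("case", "ctrl"),
    max_antecedent = 1, levels = c(-1, 1)
  )
  expect_equal(nrow(single), 3 * 2 * 2)
  expect_equal(
    single$antecedent[1:4],
    c("-1:gA", "-1:gA", "+1:gA", "+1:gA")
  )
  expect_equal(single$consequent[1:2], c("case", "ctrl"))

  pairs <- enumerate_candidates(labels, c("case", "ctrl"),
    max_antecedent = 2, levels = c(-1, 0, 1)
  )
  expect_equal(nrow(pairs), choose(3, 2) * 3 * 3 * 2)
  expect_equal(pairs$antecedent[1], "-1:gA,-1:gB")

  lone <- enumerate_candidates(labels[1, ], "case", max_antecedent = 2)
  expect_equal(nrow(lone), 0)
  expect_error(enumerate_candidates(labels, "case", max_antecedent = 3), "1 or 2")
})

test_that("rule tallies match hand counts on the four-sample toy", {
  counts <- count_rule(toy_labels(), toy_groups(), "+1:geneX", "case")
  expect_equal(counts, rule_counts(4, 2, 2, 2))
  expect_equal(count_rule(toy_labels(), toy_groups(), "+1:geneX", "ctrl")$n_AB, 0)
  none <- count_rule(toy_labels(), toy_groups(), "0:geneX", "case")
  expect_equal(none$n_A, 1)
  expect_error(count_rule(toy_labels(), toy_groups(), "+1:nope", "case"), "unknown gene")
  expect_error(count_rule(toy_labels(), toy_groups(), "+1:geneX", "dog"), "unknown class")
  expect_error(parse_antecedent("bogus"), "malformed")
})

test_that("a perfectly class-split gene yields a meaningful rule", {
  labels <- make_labels(matrix(rep(c(1L, 0L), each = 8), nrow = 1),
    gene_ids = "marker"
  )
  groups <- make_groups(rep(c("case", "ctrl"), each = 8))
  rules <- mine_quiet(labels, groups, alpha = 0.05)
  hit <- dplyr::filter(rules, antecedent == "+1:marker", consequent == "case")
  expect_equal(hit$support, 0.5)
  expect_equal(hit$confidence, 1)
  expect_equal(hit$s_min, minimum_support(0.5, 0.5, 16, 0.05))
  expect_lt(hit$s_min, 0.43)
  expect_true(hit$meaningful)
})

test_that("rules whose antecedent never occurs are dropped", {
  labels <- make_labels(matrix(c(1L, 1L, 0L, 0L), nrow = 1), gene_ids = "g")
  rules <- mine_quiet(labels, make_groups(c("a", "a", "b", "b")))
  expect_false("-1:g" %in% rules$antecedent)
  expect_true("+1:g" %in% rules$antecedent)
})

test_that("fixed mode at (0, 0) keeps every co-occurring rule", {
  ds <- random_dataset(6, 12, seed = 21)
  rules <- mine_quiet(ds$labels, ds$groups,
    mode = "fixed",
    min_support = 0, min_confidence = 0
  )
  expect_true(all(rules$meaningful == (rules$n_AB > 0)))
})

test_that("per-rule flags equal direct threshold comparison (fixed == dynamic contract)", {
  ds <- random_dataset(8, 16, seed = 31)
  rules <- mine_quiet(ds$labels, ds$groups, alpha = 0.1)
  expect_equal(
    rules$meaningful,
    rules$support > rules$s_min & rules$confidence > rules$c_min
  )
  # support never exceeds confidence; both are proportions
  expect_true(all(rules$support <= rules$confidence + 1e-12))
  expect_true(all(rules$support >= 0 & rules$confidence <= 1))
})

test_that("meaningful sets are nested across significance levels", {
  for (seed in c(41, 42, 43)) {
    ds <- random_dataset(10, 20, seed = seed)
    strict <- mine_quiet(ds$labels, ds$groups, alpha = 0.01)
    loose <- mine_quiet(ds$labels, ds$groups, alpha = 0.10)
    key <- function(r) paste(r$antecedent, r$consequent)[r$meaningful]
    expect_true(all(key(strict) %in% key(loose)))
  }
})

test_that("dynamic thresholds depend only on the marginals, never the joint count", {
  ds <- random_dataset(12, 18, seed = 51)
  rules <- mine_quiet(ds$labels, ds$groups, levels = c(-1, 0, 1))
  per_marginal <- rules |>
    dplyr::group_by(n_A, n_B) |>
    dplyr::summarise(
      s_spread = diff(range(s_min)),
      c_spread = diff(range(c_min)), .groups = "drop"
    )
  expect_true(all(per_marginal$s_spread == 0))
  expect_true(all(per_marginal$c_spread == 0))
})

test_that("the back-solve screen never changes the meaningful rule set", {
  for (seed in 61:80) {
    ds <- random_dataset(8, 14, seed = seed)
    plain <- mine_quiet(ds$labels, ds$groups, alpha = 0.05)
    pruned <- mine_quiet(ds$labels, ds$groups,
      alpha = 0.05,
      prune_by_backsolve = TRUE
    )
    key <- function(r) sort(paste(r$antecedent, r$consequent)[r$meaningful])
    expect_identical(key(plain), key(pruned))
  }
})

test_that("double-antecedent tallies agree with explicit counting", {
  ds <- random_dataset(5, 12, seed = 91)
  rules <- mine_quiet(ds$labels, ds$groups,
    max_antecedent = 2,
    levels = c(-1, 1)
  )
  some <- rules[unique(round(seq(1, nrow(rules), length.out = 10))), ]
  for (i in seq_len(nrow(some))) {
    direct <- count_rule(
      ds$labels, ds$groups,
      some$antecedent[i], some$consequent[i]
    )
    expect_equal(some$n_A[i], direct$n_A)
    expect_equal(some$n_AB[i], direct$n_AB)
    expect_equal(some$n_B[i], direct$n_B)
  }
})

test_that("mining validates its inputs and reports the candidate count", {
  ds <- random_dataset(4, 8, seed = 101)
  expect_error(mine_quiet(ds$labels, ds$groups, alpha = 0.7), "alpha")
  one_class <- make_groups(rep("only", 8))
  expect_error(mine_quiet(ds$labels, one_class), "two classes")
  expect_error(
    mine_quiet(ds$labels, ds$groups, mode = "fixed"),
    "min_support"
  )
  expect_message(
    mine_rules(ds$labels, ds$groups),
    class = "darules_candidate_count"
  )
})

test_that("rule sets tidy and glance like fitted objects", {
  ds <- random_dataset(6, 10, seed = 111)
  rules <- mine_quiet(ds$labels, ds$groups)
  g <- glance(rules)
  expect_equal(g$n_candidates, attr(rules, "n_candidates"))
  expect_equal(g$n_meaningful, sum(rules$meaningful))
  expect_s3_class(tidy(rules), "tbl_df")
})
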