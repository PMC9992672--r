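test_that("equal-frequency tertiles assign low/medium/high with lower-bin ties", {
  x <- matrix(c(0.1, 0.2, 0.5, 0.6, 0.9, 1.0), ncol = 1,
              dimnames = list(NULL, "fX"))
  tt <- discretize(x, rep(c("early", "late"), 3))
  items <- vapply(tt$transactions, `[[`, "", 1)
  expect_equal(items, paste0("fX=", c("low", "low", "medium", "medium",
                                      "high", "high")))
})

test_that("transactions carry one level item per feature plus one stage item", {
  d <- toy_dataset(n_per_class = 10, n_features = 6, seed = 3)
  mm <- fit_minmax(d$values)
  tt <- discretize(apply_minmax(d$values, mm), d$labels)
  expect_equal(tt$n, 20)
  expect_true(all(lengths(tt$transactions) == 7))
  stages <- vapply(tt$transactions, function(tx) {
    tx[startsWith(tx, "stage=")]
  }, "")
  expect_equal(stages, paste0("stage=", as.character(d$labels)))
  all_early <- discretize(apply_minmax(d$values, mm), rep("early", 20))
  expect_true(all(vapply(all_early$transactions, function(tx) {
    "stage=early" %in% tx
  }, TRUE)))
  # constant columns degrade gracefully through the quantile thresholds
  xconst <- matrix(c(rep(0.5, 6), 0.1, 0.2, 0.3, 0.4, 0.5, 0.6), ncol = 2,
                   dimnames = list(NULL, c("c", "v")))
  expect_silent(discretize(xconst, rep("late", 6)))
})

test_that("frequent itemsets are exactly those above the support threshold", {
  tt <- transaction_table(list(c("A", "B"), "A", "B"))
  fi <- mine_frequent_itemsets(tt, min_support = 0.5, max_length = 3)
  expect_equal(vapply(fi$items, paste, "", collapse = ","), c("A", "B"))
  expect_equal(fi$support, c(2 / 3, 2 / 3))

  fi1 <- mine_frequent_itemsets(tt, min_support = 1 / 3, max_length = 1)
  expect_equal(nrow(fi1), 2)
  expect_true(all(fi1$length == 1))
})

test_that("FP-Growth equals exhaustive enumeration on random tables", {
  set.seed(52)
  for (i in 1:30) {
    txs <- random_transactions(sample(10:60, 1), sample(4:10, 1))
    ms <- runif(1, 0.1, 0.5)
    ml <- sample(2:4, 1)
    mined <- mine_frequent_itemsets(transaction_table(txs), ms, ml)
    brute <- oracle_itemsets(lapply(txs, unique), ms, ml)
    expect_equal(itemset_signature(
      lapply(seq_len(nrow(mined)), function(r) list(items = mined$items[[r]]))),
      itemset_signature(brute))
    key <- vapply(brute, function(s) paste(sort(s$items), collapse = "\x1f"), "")
    bcnt <- setNames(vapply(brute, `[[`, 0, "count"), key)
    mkey <- vapply(mined$items, paste, "", collapse = "\x1f")
    expect_equal(unname(bcnt[mkey]), mined$count)
  }
})

test_that("every subset of a frequent itemset is frequent with larger support", {
  set.seed(61)
  txs <- random_transactions(50, 8, p_item = 0.5)
  fi <- mine_frequent_itemsets(transaction_table(txs), 0.2, 4)
  key <- vapply(fi$items, paste, "", collapse = "\x1f")
  sup <- setNames(fi$support, key)
  for (r in which(fi$length >= 2)) {
    items <- fi$items[[r]]
    for (drop in seq_along(items)) {
      subkey <- paste(sort(items[-drop]), collapse = "\x1f")
      expect_true(subkey %in% key)
      expect_gte(sup[[subkey]], fi$support[r])
    }
  }
})

test_that("rule measures follow the support/confidence/lift definitions", {
  tt <- transaction_table(list(c("A", "B", "S"), c("A", "B", "S"),
                               c("A", "S"), "B", c("A", "B")))
  fi <- mine_frequent_itemsets(tt, min_support = 0.2, max_length = 3)
  rules <- generate_rules(fi, min_lift = 0)
  akey <- vapply(rules$antecedent, paste, "", collapse = ";")
  ckey <- vapply(rules$consequent, paste, "", collapse = ";")
  ab <- which(akey == "A" & ckey == "B")
  expect_length(ab, 1)
  expect_equal(rules$support[ab], 0.6)
  expect_equal(rules$confidence[ab], 0.75)
  expect_equal(rules$lift[ab], 0.9375)
  # lift threshold excludes that negatively associated rule
  filtered <- generate_rules(fi, min_lift = 1.1)
  fkey <- vapply(filtered$antecedent, paste, "", collapse = ";")
  expect_false(any(fkey == "A" &
                     vapply(filtered$consequent, paste, "",
                            collapse = ";") == "B"))
})

test_that("independent items have lift exactly one", {
  tt <- transaction_table(list(c("A", "C"), "A", "C", "Z"))
  fi <- mine_frequent_itemsets(tt, min_support = 0.25, max_length = 2)
  rules <- generate_rules(fi, min_lift = 0)
  akey <- vapply(rules$antecedent, paste, "", collapse = ";")
  ckey <- vapply(rules$consequent, paste, "", collapse = ";")
  ac <- which(akey == "A" & ckey == "C")
  expect_equal(rules$lift[ac], 1)
})

test_that("lift is symmetric and identities hold to 1e-12", {
  set.seed(71)
  txs <- random_transactions(60, 8, p_item = 0.5)
  fi <- mine_frequent_itemsets(transaction_table(txs), 0.15, 4)
  rules <- generate_rules(fi, min_lift = 0)
  key <- vapply(fi$items, paste, "", collapse = "\x1f")
  sup <- setNames(fi$support, key)
  lift_of <- function(a, c_) {
    i <- which(vapply(rules$antecedent, function(x) setequal(x, a), TRUE) &
                 vapply(rules$consequent, function(x) setequal(x, c_), TRUE))
    rules$lift[i]
  }
  for (r in seq_len(min(nrow(rules), 200))) {
    a <- rules$antecedent[[r]]; c_ <- rules$consequent[[r]]
    sup_a <- sup[[paste(sort(a), collapse = "\x1f")]]
    sup_c <- sup[[paste(sort(c_), collapse = "\x1f")]]
    sup_x <- sup[[paste(sort(c(a, c_)), collapse = "\x1f")]]
    expect_equal(rules$support[r], sup_x, tolerance = 1e-12)
    expect_equal(rules$confidence[r], sup_x / sup_a, tolerance = 1e-12)
    expect_equal(rules$lift[r], (sup_x / sup_a) / sup_c, tolerance = 1e-12)
    expect_equal(lift_of(c_, a), rules$lift[r], tolerance = 1e-12)
  }
})

test_that("stage-consequent filtering is by consequent only", {
  tt <- transaction_table(list(
    c("mirX=high", "stage=early"), c("mirX=high", "stage=early"),
    c("mirX=low", "stage=late"), c("mirX=low", "stage=late"),
    c("mirX=high", "stage=early")))
  fi <- mine_frequent_itemsets(tt, min_support = 0.3, max_length = 2)
  rules <- generate_rules(fi, min_lift = 0)
  early <- filter_stage_rules(rules, "early")
  expect_true(all(vapply(early$consequent, function(x) {
    "stage=early" %in% x
  }, TRUE)))
  expect_false(any(vapply(early$antecedent, function(x) {
    any(startsWith(x, "stage="))
  }, TRUE)))
  akeys <- vapply(early$antecedent, paste, "", collapse = ";")
  expect_true("mirX=high" %in% akeys)
})

test_that("a planted perfect association appears with confidence one", {
  set.seed(81)
  n <- 40
  labels <- rep(c("early", "late"), each = n / 2)
  marker <- ifelse(labels == "late", 0.9, 0.1) + runif(n, -0.05, 0.05)
  noise <- matrix(runif(3 * n), n, 3)
  x <- cbind(feat = marker, noise)
  colnames(x) <- c("feat", paste0("n", 1:3))
  rownames(x) <- sprintf("s%02d", 1:n)
  tt <- discretize(apply_minmax(x, fit_minmax(x)), labels)
  fi <- mine_frequent_itemsets(tt, min_support = 0.3, max_length = 3)
  rules <- generate_rules(fi, min_lift = 1.1)
  late <- filter_stage_rules(rules, "late")
  akeys <- vapply(late$antecedent, paste, "", collapse = ";")
  hit <- which(akeys == "feat=high")
  expect_length(hit, 1)
  expect_equal(late$confidence[hit], 1.0)
  ranking <- rank_repeat_counts(late)
  expect_equal(ranking$feature_id[1], "feat")
})

test_that("repeat counts tally antecedent incidences once per rule", {
  expect_equal(nrow(rank_repeat_counts(
    generate_rules(mine_frequent_itemsets(
      transaction_table(list("A")), 1, 1), 0))), 0)
  tt <- transaction_table(list(
    c("fX=low", "fY=high", "stage=early"),
    c("fX=low", "fY=high", "stage=early"),
    c("fX=low", "fZ=low", "stage=early"),
    c("fX=low", "stage=early")))
  fi <- mine_frequent_itemsets(tt, min_support = 0.25, max_length = 3)
  rules <- filter_stage_rules(generate_rules(fi, min_lift = 0), "early")
  ranking <- rank_repeat_counts(rules)
  # brute-force recount of (rule, feature) incidences
  tally <- table(unlist(lapply(seq_len(nrow(rules)), function(i) {
    unique(sub("=[^=]*$", "", rules$antecedent[[i]]))
  })))
  expect_equal(sum(ranking$repeat_count), sum(tally))
  expect_equal(ranking$repeat_count[ranking$feature_id == "fX"],
               unname(as.integer(tally["fX"])))
  expect_equal(ranking$feature_id[1], "fX")
})

test_that("anchor rules require a known feature and respect the lift cut", {
  tt <- transaction_table(lapply(1:20, function(i) {
    if (i <= 18) c("fY=high", "fX=high") else c("fY=low", "fX=low")
  }))
  fi <- mine_frequent_itemsets(tt, min_support = 0.1, max_length = 2)
  rules <- generate_rules(fi, min_lift = 0)
  hits <- anchor_feature_rules(rules, "fX", min_lift = 1)
  akeys <- vapply(hits$antecedent, paste, "", collapse = ";")
  ckeys <- vapply(hits$consequent, paste, "", collapse = ";")
  expect_true(any(akeys == "fY=high" & ckeys == "fX=high"))
  expect_true(all(hits$lift >= 1))
  expect_equal(nrow(anchor_feature_rules(rules, "fX", min_lift = 1e6)), 0)
  expect_error(anchor_feature_rules(rules, "missing"), "unknown feature")
})

test_that("rule graphs round-trip through the edge-list file", {
  tt <- transaction_table(list(c("A=high", "stage=early"),
                               c("A=high", "stage=early"),
                               c("A=low", "stage=late")))
  fi <- mine_frequent_itemsets(tt, min_support = 0.3, max_length = 2)
  rules <- filter_stage_rules(generate_rules(fi, min_lift = 1), "early")
  expect_gte(nrow(rules), 1)
  one <- rules[1, , drop = FALSE]
  f <- tempfile(fileext = ".tsv")
  edges <- export_rule_graph(one, "stage=early", f)
  expect_equal(nrow(edges), 2)  # one antecedent edge, one consequent edge
  nodes <- unique(c(edges$source, edges$target))
  expect_length(nodes, 3)
  back <- read_rule_graph(f)
  expect_equal(back[order(back$source, back$target), ],
               edges[order(edges$source, edges$target), ],
               ignore_attr = TRUE)
  g <- rule_graph(rules, "stage=early")
  n_rules <- nrow(rules)
  n_feats <- length(unique(unlist(c(rules$antecedent))))
  expect_equal(igraph::vcount(g), n_feats + n_rules + 1)
})
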