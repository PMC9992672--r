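# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: statistics are written out from their
# defining formulas and itemset mining is exhaustive enumeration.

# Welch t statistic and two-sided p from first principles
oracle_welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  s1 <- sum((a - mean(a))^2) / (n1 - 1)
  s2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- s1 / n1 + s2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

# One-way fixed-effects ANOVA from its sum-of-squares decomposition
oracle_anova_f <- function(groups) {
  all_x <- unlist(groups)
  gm <- mean(all_x)
  bss <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  wss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups); n <- length(all_x)
  f <- (bss / (k - 1)) / (wss / (n - k))
  list(statistic = f, p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       bss = bss, wss = wss)
}

# AUC by enumerating every positive-negative pair
oracle_auc_pairs <- function(scores, labels, positive = "late") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Metric battery straight from the defining formulas
oracle_metrics <- function(truth, predicted, positive = "late") {
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fn <- sum(truth == positive & predicted != positive)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn) * 100,
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       f1_positive = tp / (tp + 0.5 * (fp + fn)),
       sensitivity = tp / (tp + fn) * 100,
       specificity = tn / (tn + fp) * 100)
}

# Exhaustive (Apriori-style) frequent itemset enumeration
oracle_itemsets <- function(transactions, min_support, max_length) {
  vocab <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  inc <- vapply(vocab, function(it) {
    vapply(transactions, function(tx) it %in% tx, TRUE)
  }, logical(n))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = n)
  out <- list()
  for (len in seq_len(min(max_length, length(vocab)))) {
    for (comb in utils::combn(length(vocab), len, simplify = FALSE)) {
      cnt <- sum(rowSums(inc[, comb, drop = FALSE]) == len)
      if (cnt / n >= min_support - 1e-9) {
        out[[length(out) + 1L]] <- list(items = vocab[comb], count = cnt)
      }
    }
  }
  out
}

itemset_signature <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s$items), collapse = "|"), ""))
}

# Rule measures recomputed by scanning the raw transactions
oracle_rule_measures <- function(transactions, antecedent, consequent) {
  n <- length(transactions)
  has <- function(items) {
    mean(vapply(transactions, function(tx) all(items %in% tx), TRUE))
  }
  sup_ac <- has(c(antecedent, consequent))
  sup_a <- has(antecedent)
  sup_c <- has(consequent)
  list(support = sup_ac, confidence = sup_ac / sup_a,
       lift = (sup_ac / sup_a) / sup_c)
}

random_transactions <- function(n_tx, n_items, p_item = 0.4) {
  vocab <- paste0("item", seq_len(n_items))
  repeat {
    txs <- lapply(seq_len(n_tx), function(i) {
      vocab[stats::runif(n_items) < p_item]
    })
    txs <- Filter(length, txs)
    if (length(txs) > 0) return(txs)
  }
}

# Small labeled toy matrix used by several tests
toy_dataset <- function(n_per_class = 20, n_features = 12, n_informative = 0,
                        effect = 0, seed = 1, constant_fraction = 0) {
  generate_dataset(synthetic_spec(
    n_early = n_per_class, n_late = n_per_class, n_features = n_features,
    n_informative = n_informative, effect_size = effect,
    constant_fraction = constant_fraction, seed = seed))
}
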