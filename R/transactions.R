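#' Discretize min--max-scaled expression into transactions
#'
#' Per feature, equal-frequency tertiles of the observed values define the
#' `low`/`medium`/`high` levels: values at or below the 1/3 quantile are
#' `low`, at or below the 2/3 quantile `medium`, else `high` (boundary ties
#' fall to the lower bin; quantiles are the default type-7 interpolation).
#' Features with fewer than three distinct values pass through the same
#' thresholds and never fail. Each sample becomes one transaction of
#' `feature=level` items plus exactly one `stage=early`/`stage=late` item.
#'
#' @param values samples-by-features matrix in `[0, 1]` (min--max
#'   normalized; see [apply_minmax()]).
#' @param labels per-sample `early`/`late` labels.
#' @return an object of class `TransactionTable`: list with `transactions`
#'   (list of character item vectors), `n` (transaction count) and `items`
#'   (the item vocabulary).
#' @export
discretize <- function(values, labels) {
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop_config("values must be min-max normalized into [0, 1]")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values) ||
      !all(labels %in% c("early", "late"))) {
    stop_config("labels must be one 'early'/'late' value per sample row")
  }
  lev <- matrix("", nrow = nrow(values), ncol = ncol(values))
  for (j in seq_len(ncol(values))) {
    q <- quantile(values[, j], c(1 / 3, 2 / 3), names = FALSE, type = 7)
    lev[, j] <- ifelse(values[, j] <= q[1], "low",
                       ifelse(values[, j] <= q[2], "medium", "high"))
  }
  feats <- colnames(values)
  transactions <- lapply(seq_len(nrow(values)), function(i) {
    c(paste0(feats, "=", lev[i, ]), paste0("stage=", labels[i]))
  })
  structure(list(transactions = transactions,
                 n = length(transactions),
                 items = sort(unique(unlist(transactions)))),
            class = "TransactionTable")
}

#' Build a transaction table from raw item lists
#'
#' Convenience constructor for mining arbitrary transactions (e.g. toy
#' examples or hand-written fixtures).
#'
#' @param transactions list of character vectors; duplicate items within a
#'   transaction are collapsed.
#' @return a `TransactionTable`.
#' @export
transaction_table <- function(transactions) {
  if (!is.list(transactions) || length(transactions) == 0L) {
    stop_config("'transactions' must be a nonempty list of item vectors")
  }
  transactions <- lapply(transactions, function(tx) unique(as.character(tx)))
  structure(list(transactions = transactions,
                 n = length(transactions),
                 items = sort(unique(unlist(transactions)))),
            class = "TransactionTable")
}

#' @export
print.TransactionTable <- function(x, ...) {
  cat(sprintf("TransactionTable: %d transactions over %d items\n",
              x$n, length(x$items)))
  invisible(x)
}
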