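# FP-Growth frequent itemset mining.
#
# The tree is held in growable parallel vectors (item, count, parent) with a
# children lookup keyed "parent|item" and a per-item header of node ids; the
# root is the implicit node 0. Items are inserted in descending global
# support order (ties alphabetical), so shared prefixes compress.

new_fptree <- function() {
  tr <- new.env(parent = emptyenv())
  tr$item <- integer(0)
  tr$count <- numeric(0)
  tr$parent <- integer(0)
  tr$children <- new.env(parent = emptyenv())
  tr$header <- new.env(parent = emptyenv())
  tr
}

fptree_insert <- function(tr, path, weight) {
  cur <- 0L
  for (it in path) {
    key <- paste0(cur, "|", it)
    id <- tr$children[[key]]
    if (is.null(id)) {
      id <- length(tr$item) + 1L
      tr$item[id] <- it
      tr$count[id] <- weight
      tr$parent[id] <- cur
      tr$children[[key]] <- id
      hk <- as.character(it)
      tr$header[[hk]] <- c(tr$header[[hk]], id)
    } else {
      tr$count[id] <- tr$count[id] + weight
    }
    cur <- id
  }
}

# Walk up from a node, collecting the prefix path (root excluded, item of
# the node itself excluded).
fptree_prefix <- function(tr, id) {
  path <- integer(0)
  cur <- tr$parent[id]
  while (cur != 0L) {
    path <- c(tr$item[cur], path)
    cur <- tr$parent[cur]
  }
  path
}

fp_mine <- function(tr, suffix, minc, max_length, out) {
  present <- as.integer(ls(tr$header))
  # process least-frequent (largest rank) first, the classic bottom-up order
  for (it in sort(present, decreasing = TRUE)) {
    nodes <- tr$header[[as.character(it)]]
    cnt <- sum(tr$count[nodes])
    if (cnt < minc) next
    itemset <- c(it, suffix)
    out$sets[[length(out$sets) + 1L]] <- sort(itemset)
    out$counts[[length(out$counts) + 1L]] <- cnt
    if (length(itemset) >= max_length) next
    # conditional pattern base for this item
    paths <- lapply(nodes, function(id) fptree_prefix(tr, id))
    weights <- tr$count[nodes]
    cond_counts <- new.env(parent = emptyenv())
    for (i in seq_along(paths)) {
      for (p in paths[[i]]) {
        k <- as.character(p)
        cond_counts[[k]] <- (cond_counts[[k]] %||% 0) + weights[i]
      }
    }
    keep <- as.integer(Filter(function(k) cond_counts[[as.character(k)]] >= minc,
                              as.integer(ls(cond_counts))))
    if (length(keep) == 0L) next
    cond <- new_fptree()
    for (i in seq_along(paths)) {
      p <- paths[[i]][paths[[i]] %in% keep]
      if (length(p) > 0) fptree_insert(cond, sort(p), weights[i])
    }
    fp_mine(cond, itemset, minc, max_length, out)
  }
}

#' Mine frequent itemsets with FP-Growth
#'
#' Returns exactly the itemsets whose support (fraction of transactions
#' containing them) is at least `min_support` and whose length is at most
#' `max_length`. The FP-tree inserts items in descending global support
#' order (alphabetical tie-break) and is mined bottom-up through
#' conditional pattern bases.
#'
#' @param transactions a `TransactionTable` (see [discretize()],
#'   [transaction_table()]).
#' @param min_support minimum support in `(0, 1]`; default 0.3.
#' @param max_length maximum itemset length; default 4.
#' @return data.frame with list-column `items` (sorted character vectors),
#'   `support`, `count` and `length`, ordered by length then items.
#' @export
mine_frequent_itemsets <- function(transactions, min_support = 0.3,
                                   max_length = 4L) {
  stopifnot(inherits(transactions, "TransactionTable"))
  min_support <- check_scalar_number(min_support, "min_support",
                                     lower = 1e-12, upper = 1)
  max_length <- check_scalar_count(max_length, "max_length")
  n <- transactions$n
  if (n == 0L) stop_config("no transactions to mine")
  minc <- min_support * n - 1e-9
  item_counts <- table(unlist(transactions$transactions))
  freq_items <- names(item_counts)[item_counts >= minc]
  if (length(freq_items) == 0L) {
    return(data.frame(items = I(list()), support = numeric(0),
                      count = numeric(0), length = integer(0)))
  }
  ord <- order(-item_counts[freq_items], freq_items)
  lev <- freq_items[ord]  # rank 1 = most frequent
  rank_of <- setNames(seq_along(lev), lev)
  tr <- new_fptree()
  for (tx in transactions$transactions) {
    r <- sort(unname(rank_of[tx[tx %in% lev]]))
    if (length(r) > 0) fptree_insert(tr, r, 1)
  }
  out <- new.env(parent = emptyenv())
  out$sets <- list()
  out$counts <- list()
  fp_mine(tr, integer(0), minc, max_length, out)
  sets <- lapply(out$sets, function(s) lev[s])
  counts <- unlist(out$counts)
  key <- vapply(sets, function(s) paste(sort(s), collapse = "\x1f"), "")
  ord2 <- order(lengths(sets), key)
  res <- data.frame(support = counts[ord2] / n,
                    count = counts[ord2],
                    length = lengths(sets)[ord2])
  res$items <- I(lapply(sets[ord2], sort))
  res <- res[, c("items", "support", "count", "length")]
  rownames(res) <- NULL
  res
}
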