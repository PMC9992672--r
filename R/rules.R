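itemset_key <- function(items) paste(sort(items), collapse = "\x1f")

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset X of length >= 2, all splits X = A ∪ C with
#' nonempty disjoint antecedent A and consequent C are scored:
#' `support = support(X)`, `confidence = support(X) / support(A)`,
#' `lift = confidence / support(C)`. Rules are kept when
#' `lift >= min_lift` and `support >= min_support` (no minimum-confidence
#' threshold is applied). Anti-monotonicity guarantees every A and C is
#' itself in the frequent set, so all supports are exact lookups.
#'
#' @param itemsets a [mine_frequent_itemsets()] result.
#' @param min_lift minimum lift; default 1.1.
#' @param min_support minimum rule support; default 0 (the mining threshold
#'   already bounds it).
#' @return data.frame of class `RuleSet` with list-columns `antecedent` and
#'   `consequent` plus `support`, `confidence`, `lift`, ordered by
#'   descending lift (ties: antecedent then consequent).
#' @export
generate_rules <- function(itemsets, min_lift = 1.1, min_support = 0) {
  sup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(itemsets))) {
    sup[[itemset_key(itemsets$items[[i]])]] <- itemsets$support[i]
  }
  ante <- list(); cons <- list()
  s <- numeric(0); cf <- numeric(0); lf <- numeric(0)
  big <- which(itemsets$length >= 2L)
  for (i in big) {
    x <- itemsets$items[[i]]
    sup_x <- itemsets$support[i]
    len <- length(x)
    for (a_size in seq_len(len - 1L)) {
      picks <- combn(len, a_size, simplify = FALSE)
      for (p in picks) {
        a <- x[p]; c_ <- x[-p]
        sup_a <- sup[[itemset_key(a)]]
        sup_c <- sup[[itemset_key(c_)]]
        conf <- sup_x / sup_a
        lift <- conf / sup_c
        if (lift >= min_lift - 1e-12 && sup_x >= min_support - 1e-12) {
          k <- length(s) + 1L
          ante[[k]] <- a; cons[[k]] <- c_
          s[k] <- sup_x; cf[k] <- conf; lf[k] <- lift
        }
      }
    }
  }
  res <- data.frame(support = s, confidence = cf, lift = lf)
  res$antecedent <- I(ante)
  res$consequent <- I(cons)
  res <- res[, c("antecedent", "consequent", "support", "confidence", "lift")]
  akey <- vapply(ante, paste, "", collapse = ";")
  ckey <- vapply(cons, paste, "", collapse = ";")
  ord <- order(-res$lift, akey, ckey)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("RuleSet", "data.frame")
  res
}

#' Keep the rules that conclude a given stage
#'
#' Stage-consequent rules: the consequent contains the `stage=<stage>` item
#' and the antecedent contains no stage item at all.
#'
#' @param rules a [generate_rules()] result.
#' @param stage `"early"` or `"late"`.
#' @return the filtered `RuleSet`.
#' @export
filter_stage_rules <- function(rules, stage = c("early", "late")) {
  stage <- match.arg(stage)
  target <- paste0("stage=", stage)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    target %in% rules$consequent[[i]] &&
      !any(startsWith(rules$antecedent[[i]], "stage="))
  }, TRUE)
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

item_feature <- function(items) sub("=[^=]*$", "", items)

#' Rank features by repeat count in stage rules
#'
#' Counts, per feature, the number of stage-consequent rules whose antecedent
#' contains any of its expression-level items (`low`/`medium`/`high`
#' variants aggregate; a feature counts once per rule).
#'
#' @param stage_rules a [filter_stage_rules()] result.
#' @return data.frame with `feature_id` and `repeat_count`, descending count
#'   with ties broken by feature id.
#' @export
rank_repeat_counts <- function(stage_rules) {
  if (nrow(stage_rules) == 0L) {
    return(data.frame(feature_id = character(0), repeat_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  feats <- unlist(lapply(seq_len(nrow(stage_rules)), function(i) {
    unique(item_feature(stage_rules$antecedent[[i]]))
  }))
  counts <- table(feats)
  out <- data.frame(feature_id = names(counts),
                    repeat_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$repeat_count, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rules concluding a given anchor feature
#'
#' Second-level (feature--feature) networks: keeps the rules whose consequent
#' contains any expression-level item of the anchor feature, at or above a
#' lift threshold.
#'
#' @param rules a [generate_rules()] result.
#' @param feature_id the anchor feature.
#' @param min_lift lift threshold; default 1.1.
#' @param vocabulary optional character vector of known feature ids; defaults
#'   to the features occurring in `rules`. An anchor outside the vocabulary
#'   is an error (an anchor with no concluding rules returns an empty set).
#' @return the filtered `RuleSet`.
#' @export
anchor_feature_rules <- function(rules, feature_id, min_lift = 1.1,
                                 vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- unique(item_feature(
      unlist(c(rules$antecedent, rules$consequent))))
  }
  if (!feature_id %in% vocabulary) {
    stop_config("unknown feature '%s'", feature_id)
  }
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    any(item_feature(rules$consequent[[i]]) == feature_id) &&
      rules$lift[i] >= min_lift - 1e-12
  }, TRUE)
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a rule graph as a tab-separated edge list
#'
#' Tripartite structure mirroring the rule-network figures: one
#' phenotype-or-anchor focus node, one node per rule, one node per
#' antecedent/consequent item. Edges run antecedent-item -> rule and
#' rule -> consequent-item. The file has columns `source`, `target`,
#' `source_type`, `target_type`; consequent items equal to `focus` take node
#' type `focus`.
#'
#' @param rules a nonempty `RuleSet`.
#' @param focus focus node label (e.g. `"stage=early"` or an anchor item).
#' @param path output path.
#' @return the edge data.frame, invisibly.
#' @export
export_rule_graph <- function(rules, focus, path) {
  if (nrow(rules) == 0L) stop_config("no rules to export")
  edges <- do.call(rbind, lapply(seq_len(nrow(rules)), function(i) {
    rule_id <- sprintf("rule_%03d", i)
    rbind(
      data.frame(source = rules$antecedent[[i]], target = rule_id,
                 source_type = "feature", target_type = "rule",
                 stringsAsFactors = FALSE),
      data.frame(source = rule_id, target = rules$consequent[[i]],
                 source_type = "rule",
                 target_type = ifelse(rules$consequent[[i]] == focus,
                                      "focus", "feature"),
                 stringsAsFactors = FALSE))
  }))
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read back an exported rule graph
#'
#' @param path a file written by [export_rule_graph()].
#' @return the edge data.frame.
#' @export
read_rule_graph <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Build an igraph object from a rule set
#'
#' @inheritParams export_rule_graph
#' @return an [igraph::graph_from_data_frame()] directed graph with a
#'   `type` vertex attribute (`focus`, `rule` or `feature`).
#' @export
rule_graph <- function(rules, focus) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  edges <- export_rule_graph(rules, focus, tmp)
  vtypes <- unique(rbind(
    data.frame(name = edges$source, type = edges$source_type,
               stringsAsFactors = FALSE),
    data.frame(name = edges$target, type = edges$target_type,
               stringsAsFactors = FALSE)))
  vtypes <- vtypes[!duplicated(vtypes$name), , drop = FALSE]
  igraph::graph_from_data_frame(edges[, c("source", "target")],
                                directed = TRUE, vertices = vtypes)
}

#' Write rules as CSV
#'
#' Antecedent and consequent items are semicolon-joined.
#'
#' @param rules a `RuleSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  df <- data.frame(
    antecedent = vapply(rules$antecedent, paste, "", collapse = ";"),
    consequent = vapply(rules$consequent, paste, "", collapse = ";"),
    support = rules$support, confidence = rules$confidence,
    lift = rules$lift, stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
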