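#' Two-group Welch t statistic
#'
#' Unpooled (Welch) two-sample t with sample variances (n - 1 denominator)
#' and a two-sided p-value from the t distribution at Welch--Satterthwaite
#' degrees of freedom, under the null of equal population means. Delegates to
#' [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors, each with at least two values.
#' @return list with `statistic` (t) and `p_value`.
#' @export
t_statistic <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_config("each group needs at least 2 values")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      # identical constants: no evidence against the null
      return(list(statistic = 0, p_value = 1))
    }
    stop_config("t statistic undefined: both groups have zero variance")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' One-way ANOVA F statistic
#'
#' Classic one-way fixed-effects ANOVA: F = BMS/WMS with between degrees of
#' freedom K - 1 and within degrees of freedom N - K; p-value from the F
#' distribution. Delegates to [stats::oneway.test()] with equal variances.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return list with `statistic` (F) and `p_value`.
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_config("'groups' must be a list of at least 2 numeric vectors")
  }
  if (any(lengths(groups) < 2L)) {
    stop_config("each group needs at least 2 values")
  }
  wss <- sum(vapply(groups, function(g) (length(g) - 1) * var(g), 0))
  if (wss == 0) {
    stop_config("F statistic undefined: within-group variance is zero")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(x ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Score every feature with a filter statistic
#'
#' Applies the two-group Welch t-test or one-way ANOVA F to each feature
#' column. Both filters consume the same two-class input; which one is used
#' is configuration (t-test is the conventional choice for mRNA-style data,
#' ANOVA for miRNA-style data). Features whose statistic is undefined (zero
#' variance in every group) get `NA` and sort last.
#'
#' @param values samples-by-features numeric matrix.
#' @param labels per-sample class labels (two classes).
#' @param method `"ttest"` or `"anova"`.
#' @return data.frame with `feature_id`, `statistic`, `p_value`, ordered as
#'   the input columns.
#' @export
filter_scores <- function(values, labels, method = c("ttest", "anova")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop_config("filter scoring needs exactly 2 classes, got %d",
                length(classes))
  }
  ia <- labels == classes[1]
  score_one <- function(x) {
    res <- tryCatch(
      if (method == "ttest") t_statistic(x[ia], x[!ia])
      else anova_f(list(x[ia], x[!ia])),
      stageminer_config_error = function(e) list(statistic = NA_real_,
                                                 p_value = NA_real_))
    c(res$statistic, res$p_value)
  }
  sc <- apply(values, 2, score_one)
  data.frame(feature_id = colnames(values),
             statistic = sc[1, ], p_value = sc[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep the k best features by p-value
#'
#' Stable selection: ascending p-value, ties broken by ascending feature
#' index. `NA` p-values sort last.
#'
#' @param pvalues numeric vector (optionally named by feature id).
#' @param k number of features to keep; default 25.
#' @return integer indices of the selected features in selection order,
#'   named if `pvalues` is named.
#' @export
select_top_k <- function(pvalues, k = 25L) {
  k <- check_scalar_count(k, "k")
  if (k > length(pvalues)) {
    stop_config("k = %d exceeds the number of scored features (%d)",
                k, length(pvalues))
  }
  ord <- order(pvalues, seq_along(pvalues), na.last = TRUE)
  idx <- ord[seq_len(k)]
  if (!is.null(names(pvalues))) names(idx) <- names(pvalues)[idx]
  idx
}

#' Pool per-fold filter selections
#'
#' Unions the per-inner-fold top-k feature lists and counts, per feature, how
#' many folds selected it.
#'
#' @param per_fold_lists list of character vectors of feature ids (one per
#'   inner training fold).
#' @return data.frame with `feature_id` and `selection_count`, ordered by
#'   descending count then feature id.
#' @export
union_candidates <- function(per_fold_lists) {
  if (length(per_fold_lists) == 0L || any(lengths(per_fold_lists) == 0L)) {
    stop_config("per-fold selection lists must be nonempty")
  }
  counts <- table(unlist(lapply(per_fold_lists, unique)))
  out <- data.frame(feature_id = names(counts),
                    selection_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$selection_count, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter-stage candidates for one outer fold
#'
#' Runs the configured filter on each inner training fold of one outer fold
#' (after constant cleaning and z-score normalization fitted on that inner
#' training set), keeps the top k per fold, and pools the union.
#'
#' @param values samples-by-features matrix (raw expression).
#' @param labels per-sample labels.
#' @param plan a [build_fold_plan()] result.
#' @param outer_index which outer fold.
#' @param method filter statistic, `"ttest"` or `"anova"`.
#' @param k features kept per inner fold; default 25.
#' @param remove_mask logical per-feature removal mask to apply before
#'   scoring (e.g. the fold's constant-feature mask); `NULL` for none.
#' @return list with `per_fold` (list of per-inner-fold selected id vectors)
#'   and `union` (the [union_candidates()] table).
#' @export
filter_candidates <- function(values, labels, plan, outer_index,
                              method = c("ttest", "anova"), k = 25L,
                              remove_mask = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(plan, "FoldPlan"))
  keep <- if (is.null(remove_mask)) rep(TRUE, ncol(values)) else !remove_mask
  fo <- plan$outer[[outer_index]]
  per_fold <- lapply(fo$inner, function(fi) {
    x <- values[fi$train, keep, drop = FALSE]
    zs <- fit_zscore(x)
    sc <- filter_scores(apply_zscore(x, zs), labels[fi$train], method)
    sel <- select_top_k(setNames(sc$p_value, sc$feature_id), k)
    names(sel)
  })
  list(per_fold = per_fold, union = union_candidates(per_fold))
}
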