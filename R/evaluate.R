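#' Evaluate a feature set with the classifier suite
#'
#' For every outer fold and every inner fold: constant features are removed
#' using that inner training set, z-score parameters are fitted on it, each
#' classifier is fitted on the inner training split, and the full metric
#' battery is computed on the train (inner-train), validation
#' (inner-validation) and test (outer-test) splits. The report averages each
#' metric over all inner-by-outer fits, mirroring the nested cross-validation
#' error estimate.
#'
#' @param dataset an [expression_dataset()].
#' @param feature_set character vector of feature ids to evaluate.
#' @param plan a [build_fold_plan()] for the dataset's samples.
#' @param classifiers names from the registry (see [list_classifiers()]).
#' @param seed integer seed; stochastic learners are reseeded deterministically
#'   per fit.
#' @return a `MetricsReport` data.frame with one row per classifier and
#'   split, columns `classifier`, `split`, `accuracy`, `auc_roc`,
#'   `f1_early`, `f1_late`, `mcc`, `sn`, `sp` (accuracy/Sn/Sp in percent,
#'   positive class "late"). The averaging axis is recorded in
#'   `attr(, "averaged_over")`.
#' @export
evaluate_suite <- function(dataset, feature_set, plan,
                           classifiers = c("svm", "rf", "knn", "nb", "lr",
                                           "xgboost"),
                           seed = 1L) {
  stopifnot(inherits(dataset, "ExpressionDataset"), inherits(plan, "FoldPlan"))
  specs <- lapply(classifiers, get_classifier)
  names(specs) <- classifiers
  missing <- setdiff(feature_set, dataset$feature_ids)
  if (length(missing) > 0) {
    stop_config("feature_set names unknown features: %s",
                paste(head(missing, 5), collapse = ", "))
  }
  values <- dataset$values[, feature_set, drop = FALSE]
  labels <- dataset$labels
  splits <- c("train", "validation", "test")
  acc <- list()  # per classifier: list of per-fit metric rows per split

  one_split_metrics <- function(pred, y) {
    cm <- compute_metrics(confusion_counts(y, pred$class, positive = "late"))
    c(accuracy = cm$accuracy,
      auc_roc = auc_roc(pred$score, y, positive = "late"),
      f1_early = cm$f1_negative, f1_late = cm$f1_positive,
      mcc = cm$mcc, sn = cm$sensitivity, sp = cm$specificity)
  }

  for (k in seq_len(plan$n_outer)) {
    fo <- plan$outer[[k]]
    for (j in seq_len(plan$n_inner)) {
      fi <- fo$inner[[j]]
      const <- remove_constant_features(values, fi$train)
      x <- values[, !const, drop = FALSE]
      zs <- fit_zscore(x[fi$train, , drop = FALSE])
      parts <- list(train = fi$train, validation = fi$validation,
                    test = fo$test)
      xs <- lapply(parts, function(ii) apply_zscore(x[ii, , drop = FALSE], zs))
      ys <- lapply(parts, function(ii) labels[ii])
      for (cl in classifiers) {
        fit_seed <- (seed * 1000L + k * 100L + j * 10L +
                       match(cl, classifiers)) %% .Machine$integer.max
        model <- with_seed(fit_seed, specs[[cl]]$fit(xs$train, ys$train))
        for (sp in splits) {
          pred <- with_seed(fit_seed + 1L,
                            specs[[cl]]$predict(model, xs[[sp]]))
          acc[[cl]][[sp]] <- rbind(acc[[cl]][[sp]],
                                   one_split_metrics(pred, ys[[sp]]))
        }
      }
    }
  }

  rows <- do.call(rbind, lapply(classifiers, function(cl) {
    do.call(rbind, lapply(splits, function(sp) {
      m <- colMeans(acc[[cl]][[sp]])
      data.frame(classifier = cl, split = sp, t(m),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  structure(rows,
            class = c("MetricsReport", "data.frame"),
            averaged_over = sprintf("%d outer x %d inner fits",
                                    plan$n_outer, plan$n_inner))
}

#' Write a metrics report as CSV
#'
#' Column layout mirrors the per-classifier report tables: one row per
#' classifier and split with accuracy, AUC-ROC, per-class F1, MCC,
#' sensitivity and specificity.
#'
#' @param report a `MetricsReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
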