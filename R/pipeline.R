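#' ARM parameter block
#'
#' Published defaults: minimum lift 1.1 and maximum frequent-itemset length 4
#' for both data kinds; minimum support 0.3 for miRNA-style runs and 0.2 for
#' mRNA-style runs.
#'
#' @param min_support minimum itemset support in `(0, 1]`.
#' @param min_lift minimum rule lift.
#' @param max_length maximum frequent-itemset length (bounds |A| + |C|).
#' @return validated list of class `arm_params`.
#' @export
arm_params <- function(min_support = 0.3, min_lift = 1.1, max_length = 4L) {
  structure(list(
    min_support = check_scalar_number(min_support, "min_support",
                                      lower = 1e-12, upper = 1),
    min_lift = check_scalar_number(min_lift, "min_lift", lower = 0),
    max_length = check_scalar_count(max_length, "max_length")),
    class = "arm_params")
}

#' Pipeline configuration
#'
#' Collects every stage's parameters with the published defaults pre-filled:
#' 10 outer / 5 inner folds, top-25 filter per inner fold, BPSO at
#' `alpha = beta = 2`, `theta = 0.9`, 35 particles, 100 iterations, and rule
#' mining at lift 1.1, max length 4, support 0.3. Unknown fields are
#' rejected.
#'
#' @param n_outer,n_inner fold counts.
#' @param filter_method `"ttest"` or `"anova"`.
#' @param filter_top_k features kept per inner fold.
#' @param bpso a [bpso_params()] block (or list of overrides).
#' @param classifiers registry names for the evaluation suite.
#' @param arm an [arm_params()] block (or list of overrides).
#' @param seed global seed; fans out deterministically to every stochastic
#'   stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_outer = 10L, n_inner = 5L,
                            filter_method = c("ttest", "anova"),
                            filter_top_k = 25L,
                            bpso = bpso_params(),
                            classifiers = c("svm", "rf", "knn", "nb", "lr",
                                            "xgboost"),
                            arm = arm_params(),
                            seed = 1L) {
  if (is.list(bpso) && !inherits(bpso, "bpso_params")) {
    bpso <- do.call(bpso_params, bpso)
  }
  if (is.list(arm) && !inherits(arm, "arm_params")) {
    arm <- do.call(arm_params, arm)
  }
  cfg <- list(n_outer = check_scalar_count(n_outer, "n_outer", minimum = 2L),
              n_inner = check_scalar_count(n_inner, "n_inner", minimum = 2L),
              filter_method = match.arg(filter_method),
              filter_top_k = check_scalar_count(filter_top_k, "filter_top_k"),
              bpso = bpso,
              classifiers = as.character(classifiers),
              arm = arm,
              seed = check_scalar_count(seed, "seed", minimum = 0L))
  for (cl in cfg$classifiers) get_classifier(cl)  # fail fast on unknowns
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `bpso` and `arm`
#' are nested maps. Unknown keys (top-level or nested) are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_config("unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

derive_seed <- function(seed, offset) {
  (seed * 97L + offset) %% 2147483647L
}

write_stage_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Chains the five stages on one labeled expression dataset:
#' nested-CV planning; per-outer-fold constant cleaning (union of the fold's
#' inner-training constant masks) and per-inner-fold filter ranking with
#' union pooling; binary PSO per outer fold over that fold's candidates,
#' consolidated across folds by union; classifier-suite evaluation of the
#' consolidated features; and association rule mining on the min--max scaled,
#' discretized full matrix restricted to those features, with stage-rule
#' rankings and rule graphs.
#'
#' All outputs are written under `out_dir`: `fold_plan.json`,
#' `filter_candidates.tsv`, `bpso_trace.csv`, `selected_features.tsv`,
#' `metrics.csv`, `rules.csv`, `ranking.tsv`, `rule_graph_early.tsv`,
#' `rule_graph_late.tsv` and a `manifest.json` holding the configuration,
#' derived stage seeds and per-file checksums; rerunning with the same
#' dataset and configuration reproduces the manifest byte for byte.
#'
#' @param dataset an [expression_dataset()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results: `plan`,
#'   `candidates` (per outer fold), `filter_union`, `bpso` (per outer fold),
#'   `selected`, `metrics`, `rules`, `ranking_early`, `ranking_late`,
#'   `out_dir`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = tempfile("stageminer_run_")) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("stageminer_stage_error", "error"),
        stage = name))
    })
  }
  values <- dataset$values
  labels <- dataset$labels

  plan <- stage("preprocess", {
    p <- build_fold_plan(labels, config$n_outer, config$n_inner,
                         seed = derive_seed(config$seed, 1L))
    write_fold_plan(p, dataset$sample_ids, file.path(out_dir, "fold_plan.json"))
    p
  })

  filt <- stage("filter", {
    per_fold <- lapply(seq_len(plan$n_outer), function(k) {
      fo <- plan$outer[[k]]
      masks <- lapply(fo$inner, function(fi) {
        remove_constant_features(values, fi$train)
      })
      remove <- Reduce(`|`, masks)
      fc <- filter_candidates(values, labels, plan, k,
                              method = config$filter_method,
                              k = config$filter_top_k,
                              remove_mask = remove)
      fc$remove_mask <- remove
      fc
    })
    pooled <- union_candidates(unlist(lapply(per_fold,
                                             function(f) f$per_fold),
                               recursive = FALSE))
    # report-only annotation: the candidates' filter scores on the full data
    sc <- filter_scores(values[, pooled$feature_id, drop = FALSE], labels,
                        config$filter_method)
    pooled$statistic <- sc$statistic[match(pooled$feature_id, sc$feature_id)]
    pooled$p_value <- sc$p_value[match(pooled$feature_id, sc$feature_id)]
    pooled <- pooled[, c("feature_id", "statistic", "p_value",
                         "selection_count")]
    write_stage_tsv(pooled, file.path(out_dir, "filter_candidates.tsv"))
    list(per_fold = per_fold, pooled = pooled)
  })

  bpso_res <- stage("bpso", {
    res <- lapply(seq_len(plan$n_outer), function(k) {
      cand <- filt$per_fold[[k]]$union$feature_id
      inner_data <- prepare_inner_data(values, labels, plan, k, cand)
      run_bpso(inner_data, params = config$bpso,
               seed = derive_seed(config$seed, 100L + k))
    })
    trace <- do.call(rbind, lapply(seq_along(res), function(k) {
      data.frame(outer_fold = k,
                 iteration = seq_along(res[[k]]$trace) - 1L,
                 best_fitness = res[[k]]$trace)
    }))
    write.table(trace, file.path(out_dir, "bpso_trace.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    res
  })

  selected <- stage("consolidate", {
    sel <- consolidate_selection(lapply(bpso_res, `[[`, "best_position"))
    write_stage_tsv(sel, file.path(out_dir, "selected_features.tsv"))
    sel
  })

  metrics <- stage("classify", {
    rep <- evaluate_suite(dataset, selected$feature_id, plan,
                          classifiers = config$classifiers,
                          seed = derive_seed(config$seed, 500L))
    write_metrics_report(rep, file.path(out_dir, "metrics.csv"))
    rep
  })

  arm_out <- stage("arm", {
    x <- values[, selected$feature_id, drop = FALSE]
    const <- remove_constant_features(x, seq_len(nrow(x)))
    x <- x[, !const, drop = FALSE]
    mm <- fit_minmax(x)
    tt <- discretize(apply_minmax(x, mm), labels)
    itemsets <- mine_frequent_itemsets(tt,
                                       min_support = config$arm$min_support,
                                       max_length = config$arm$max_length)
    rules <- generate_rules(itemsets, min_lift = config$arm$min_lift)
    write_rules(rules, file.path(out_dir, "rules.csv"))
    early <- filter_stage_rules(rules, "early")
    late <- filter_stage_rules(rules, "late")
    rank_e <- rank_repeat_counts(early)
    rank_l <- rank_repeat_counts(late)
    ranking <- merge(setNames(rank_e, c("feature_id", "early_repeat_count")),
                     setNames(rank_l, c("feature_id", "late_repeat_count")),
                     by = "feature_id", all = TRUE)
    ranking[is.na(ranking)] <- 0L
    ranking <- ranking[order(-(ranking$early_repeat_count +
                                 ranking$late_repeat_count),
                             ranking$feature_id), , drop = FALSE]
    rownames(ranking) <- NULL
    write_stage_tsv(ranking, file.path(out_dir, "ranking.tsv"))
    graph_or_placeholder <- function(stage_rules, focus, path) {
      if (nrow(stage_rules) > 0) {
        export_rule_graph(stage_rules, focus, path)
      } else {
        write_stage_tsv(data.frame(source = character(0),
                                   target = character(0),
                                   source_type = character(0),
                                   target_type = character(0)), path)
      }
    }
    graph_or_placeholder(early, "stage=early",
                         file.path(out_dir, "rule_graph_early.tsv"))
    graph_or_placeholder(late, "stage=late",
                         file.path(out_dir, "rule_graph_late.tsv"))
    list(rules = rules, ranking_early = rank_e, ranking_late = rank_l,
         ranking = ranking)
  })

  stage("manifest", {
    outputs <- c("fold_plan.json", "filter_candidates.tsv", "bpso_trace.csv",
                 "selected_features.tsv", "metrics.csv", "rules.csv",
                 "ranking.tsv", "rule_graph_early.tsv", "rule_graph_late.tsv")
    sums <- tools::md5sum(file.path(out_dir, outputs))
    manifest <- list(
      package = "stageminer",
      config = unclass_deep(config),
      n_samples = nrow(values),
      n_features = ncol(values),
      stage_seeds = list(fold_plan = derive_seed(config$seed, 1L),
                         bpso = vapply(seq_len(plan$n_outer), function(k) {
                           derive_seed(config$seed, 100L + k)
                         }, 0L),
                         classify = derive_seed(config$seed, 500L)),
      checksums = as.list(setNames(unname(sums), outputs)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(plan = plan,
                 candidates = lapply(filt$per_fold, `[[`, "union"),
                 filter_union = filt$pooled,
                 bpso = bpso_res,
                 selected = selected,
                 metrics = metrics,
                 rules = arm_out$rules,
                 ranking_early = arm_out$ranking_early,
                 ranking_late = arm_out$ranking_late,
                 ranking = arm_out$ranking,
                 out_dir = out_dir))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
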