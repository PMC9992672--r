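#' Build a stratified nested cross-validation plan
#'
#' Splits the samples into `n_outer` disjoint test folds; for each outer fold
#' the remaining samples (the outer-train set) are further split into
#' `n_inner` disjoint validation folds with complementary inner training
#' sets. All splits are stratified: each fold's class ratio is within one
#' sample of the global ratio. The plan is a pure function of `labels`,
#' the fold counts and `seed`.
#'
#' @param labels per-sample class labels (`early`/`late`, or any two or more
#'   classes).
#' @param n_outer number of outer (test) folds; default 10.
#' @param n_inner number of inner (validation) folds per outer fold;
#'   default 5.
#' @param seed integer seed.
#' @return an object of class `FoldPlan`: a list with `n_outer`, `n_inner`,
#'   `n_samples`, `seed` and `outer`, a list of per-outer-fold lists holding
#'   integer sample indices `test`, `train`, and `inner` — itself a list of
#'   `(train, validation)` index pairs partitioning the outer-train set.
#' @export
build_fold_plan <- function(labels, n_outer = 10L, n_inner = 5L, seed = 1L) {
  n_outer <- check_scalar_count(n_outer, "n_outer", minimum = 2L)
  n_inner <- check_scalar_count(n_inner, "n_inner", minimum = 2L)
  seed <- check_scalar_count(seed, "seed", minimum = 0L)
  labels <- as.character(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < n_outer)) {
    stop_config("class '%s' has %d samples, fewer than n_outer = %d",
                names(tab)[which.min(tab)], min(tab), n_outer)
  }
  with_seed(seed, {
    assign_strat <- function(idx_by_class, k) {
      fold <- integer(0)
      idx <- integer(0)
      for (cl_idx in idx_by_class) {
        cl_idx <- cl_idx[sample.int(length(cl_idx))]
        fold <- c(fold, rep_len(seq_len(k), length(cl_idx)))
        idx <- c(idx, cl_idx)
      }
      split(idx, fold)
    }
    by_class <- split(seq_len(n), labels)
    outer_test <- assign_strat(by_class, n_outer)
    outer <- lapply(seq_len(n_outer), function(k) {
      test <- sort(outer_test[[k]])
      train <- setdiff(seq_len(n), test)
      tr_by_class <- split(train, labels[train])
      if (any(lengths(tr_by_class) < n_inner)) {
        stop_config("outer-train set of fold %d has a class smaller than n_inner = %d",
                    k, n_inner)
      }
      inner_val <- assign_strat(tr_by_class, n_inner)
      inner <- lapply(seq_len(n_inner), function(j) {
        validation <- sort(inner_val[[j]])
        list(train = setdiff(train, validation), validation = validation)
      })
      list(test = test, train = train, inner = inner)
    })
    structure(list(n_outer = n_outer, n_inner = n_inner, n_samples = n,
                   seed = seed, outer = outer),
              class = "FoldPlan")
  })
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat(sprintf("FoldPlan: %d samples, %d outer x %d inner folds (seed %d)\n",
              x$n_samples, x$n_outer, x$n_inner, x$seed))
  invisible(x)
}

#' Check the structural invariants of a fold plan
#'
#' Verifies that outer test folds partition the samples, that each outer
#' fold's inner validation folds partition its outer-train set, and that no
#' test index leaks into any inner split of its own outer fold.
#'
#' @param plan a [build_fold_plan()] result.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_fold_plan <- function(plan) {
  stopifnot(inherits(plan, "FoldPlan"))
  all_idx <- seq_len(plan$n_samples)
  tests <- lapply(plan$outer, `[[`, "test")
  if (any(duplicated(unlist(tests)))) stop("outer test folds overlap")
  if (!setequal(unlist(tests), all_idx)) {
    stop("outer test folds do not cover all samples")
  }
  for (k in seq_len(plan$n_outer)) {
    fo <- plan$outer[[k]]
    if (!setequal(fo$train, setdiff(all_idx, fo$test))) {
      stop(sprintf("outer fold %d: train is not the complement of test", k))
    }
    vals <- lapply(fo$inner, `[[`, "validation")
    if (any(duplicated(unlist(vals)))) {
      stop(sprintf("outer fold %d: inner validation folds overlap", k))
    }
    if (!setequal(unlist(vals), fo$train)) {
      stop(sprintf("outer fold %d: inner validation folds do not cover outer-train", k))
    }
    for (j in seq_len(plan$n_inner)) {
      fi <- fo$inner[[j]]
      if (!setequal(fi$train, setdiff(fo$train, fi$validation))) {
        stop(sprintf("outer fold %d inner fold %d: train/validation mismatch", k, j))
      }
      if (length(intersect(fo$test, c(fi$train, fi$validation))) > 0) {
        stop(sprintf("outer fold %d inner fold %d: test index leaked", k, j))
      }
    }
  }
  invisible(TRUE)
}

#' Serialize or restore a fold plan
#'
#' Written as JSON keyed by sample ids so a run is exactly resumable.
#'
#' @param plan a `FoldPlan`.
#' @param sample_ids character ids, one per sample index.
#' @param path file path.
#' @return `write_fold_plan()` returns `path` invisibly; `read_fold_plan()`
#'   returns the `FoldPlan` (with indices mapped back through `sample_ids`).
#' @export
write_fold_plan <- function(plan, sample_ids, path) {
  stopifnot(inherits(plan, "FoldPlan"), length(sample_ids) == plan$n_samples)
  ser <- list(
    n_outer = plan$n_outer, n_inner = plan$n_inner,
    n_samples = plan$n_samples, seed = plan$seed,
    outer = lapply(plan$outer, function(fo) {
      list(test = sample_ids[fo$test], train = sample_ids[fo$train],
           inner = lapply(fo$inner, function(fi) {
             list(train = sample_ids[fi$train],
                  validation = sample_ids[fi$validation])
           }))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path, sample_ids) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_idx <- function(ids) {
    idx <- match(unlist(ids), sample_ids)
    if (anyNA(idx)) stop_parse("fold plan names unknown sample ids")
    idx
  }
  outer <- lapply(ser$outer, function(fo) {
    list(test = to_idx(fo$test), train = to_idx(fo$train),
         inner = lapply(fo$inner, function(fi) {
           list(train = to_idx(fi$train), validation = to_idx(fi$validation))
         }))
  })
  structure(list(n_outer = ser$n_outer, n_inner = ser$n_inner,
                 n_samples = ser$n_samples, seed = ser$seed, outer = outer),
            class = "FoldPlan")
}
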