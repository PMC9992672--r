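#' Describe a synthetic two-class expression dataset
#'
#' A `SyntheticSpec` fixes every knob of the generator: sample counts per
#' class, feature count, how many features carry a planted class difference,
#' the size of that difference, the log-normal null model, and the fraction of
#' features emitted as constants (to exercise the cleaning step).
#'
#' The base model draws each feature's log-scale location uniformly from
#' `base_distribution$meanlog_range` with common log-scale spread
#' `base_distribution$sdlog`, mimicking the right skew of FPKM-like
#' abundances. Informative features shift the late-class location by
#' `effect_size * sdlog` (sign alternating per feature), so the planted
#' difference is `effect_size` within-class standard deviations on the log
#' scale.
#'
#' @param n_early,n_late samples per class.
#' @param n_features total feature count.
#' @param n_informative number of planted differential features
#'   (`<= n_features` after removing constants).
#' @param effect_size class mean shift in units of within-class SD (log
#'   scale); `>= 0`.
#' @param base_distribution list with `meanlog_range` (length-2 numeric) and
#'   `sdlog` (positive scalar).
#' @param constant_fraction fraction of features emitted with a single
#'   constant value across all samples; in `[0, 1)`.
#' @param seed integer random seed; generation is a pure function of the spec.
#' @param id_style `"ensg"` for ENSG-like transcript ids, `"mir"` for
#'   hsa-mir-like ids.
#' @return an object of class `SyntheticSpec`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_early, n_late, n_features,
                           n_informative = 0L,
                           effect_size = 0,
                           base_distribution = list(meanlog_range = c(0, 4),
                                                    sdlog = 0.5),
                           constant_fraction = 0,
                           seed = 1L,
                           id_style = c("ensg", "mir")) {
  spec <- list(
    n_early = check_scalar_count(n_early, "n_early"),
    n_late = check_scalar_count(n_late, "n_late"),
    n_features = check_scalar_count(n_features, "n_features"),
    n_informative = check_scalar_count(n_informative, "n_informative",
                                       minimum = 0L),
    effect_size = check_scalar_number(effect_size, "effect_size", lower = 0),
    base_distribution = base_distribution,
    constant_fraction = check_scalar_number(constant_fraction,
                                            "constant_fraction",
                                            lower = 0, upper = 1,
                                            open_upper = TRUE),
    seed = check_scalar_count(seed, "seed", minimum = 0L),
    id_style = match.arg(id_style)
  )
  if (spec$n_informative > spec$n_features) {
    stop_config("'n_informative' (%d) exceeds 'n_features' (%d)",
                spec$n_informative, spec$n_features)
  }
  bd <- spec$base_distribution
  if (!is.list(bd) || length(bd$meanlog_range) != 2L ||
      !is.numeric(bd$meanlog_range) || diff(bd$meanlog_range) < 0 ||
      !is.numeric(bd$sdlog) || length(bd$sdlog) != 1L || bd$sdlog <= 0) {
    stop_config(paste0("'base_distribution' must be list(meanlog_range = ",
                       "c(lo, hi), sdlog = s > 0)"))
  }
  n_const <- floor(spec$constant_fraction * spec$n_features)
  if (spec$n_informative > spec$n_features - n_const) {
    stop_config(paste0("'n_informative' (%d) does not fit among the %d ",
                       "non-constant features implied by 'constant_fraction'"),
                spec$n_informative, spec$n_features - n_const)
  }
  structure(spec, class = "SyntheticSpec")
}

make_feature_ids <- function(n, style) {
  switch(style,
         ensg = sprintf("ENSG%011d.1", seq_len(n)),
         mir = sprintf("hsa-mir-%d", seq_len(n)))
}

#' Construct an expression dataset object
#'
#' Bundles a samples-by-features matrix of non-negative values with per-sample
#' early/late labels and optional bookkeeping about planted (truth) and
#' constant features.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   unique row (sample) and column (feature) names, all values finite and
#'   non-negative.
#' @param labels character or factor of `"early"`/`"late"`, one per sample.
#' @param truth optional character vector of planted-informative feature ids.
#' @param constant_features optional character vector of constant feature ids.
#' @return an object of class `ExpressionDataset` with elements `values`,
#'   `labels` (factor with levels early, late), `feature_ids`, `sample_ids`,
#'   `truth`, `constant_features`.
#' @export
expression_dataset <- function(values, labels, truth = NULL,
                               constant_features = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_config("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_config("'values' must carry sample (row) and feature (column) names")
  }
  if (anyDuplicated(colnames(values))) {
    stop_config("duplicate feature ids: %s",
                paste(unique(colnames(values)[duplicated(colnames(values))]),
                      collapse = ", "))
  }
  if (anyDuplicated(rownames(values))) {
    stop_config("duplicate sample ids")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_config("'values' must be finite and non-negative")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop_config("label count (%d) does not match sample count (%d)",
                length(labels), nrow(values))
  }
  if (!all(labels %in% c("early", "late"))) {
    stop_config("labels must be 'early' or 'late'")
  }
  if (!is.null(truth) && !all(truth %in% colnames(values))) {
    stop_config("'truth' names features absent from the matrix")
  }
  structure(list(values = values,
                 labels = factor(labels, levels = c("early", "late")),
                 feature_ids = colnames(values),
                 sample_ids = rownames(values),
                 truth = truth,
                 constant_features = constant_features),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d features (%d early, %d late)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "early"), sum(x$labels == "late")))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted informative features: %d\n", length(x$truth)))
  }
  if (!is.null(x$constant_features)) {
    cat(sprintf("  constant features: %d\n", length(x$constant_features)))
  }
  invisible(x)
}

#' Generate a synthetic two-class expression dataset
#'
#' Draws a log-normal expression matrix per the spec: every feature gets its
#' own log-scale location; planted informative features additionally shift the
#' late-class location by `effect_size * sdlog` with alternating sign;
#' constant features repeat one value across all samples. Which features are
#' informative or constant is itself a seeded random draw, so informative
#' columns are interleaved with noise columns.
#'
#' @param spec a [synthetic_spec()].
#' @return an [expression_dataset()] whose `truth` element lists exactly the
#'   planted informative feature ids and whose `constant_features` element
#'   lists the constant columns.
#' @examples
#' d <- generate_dataset(synthetic_spec(20, 20, 50, n_informative = 5,
#'                                      effect_size = 2, seed = 1))
#' d
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "SyntheticSpec")) {
    spec <- do.call(synthetic_spec, as.list(spec))
  }
  n <- spec$n_early + spec$n_late
  m <- spec$n_features
  with_seed(spec$seed, {
    feature_ids <- make_feature_ids(m, spec$id_style)
    sample_ids <- sprintf("sample_%04d", seq_len(n))
    labels <- c(rep("early", spec$n_early), rep("late", spec$n_late))
    n_const <- floor(spec$constant_fraction * m)
    roles <- rep("noise", m)
    const_idx <- if (n_const > 0) sample.int(m, n_const) else integer(0)
    roles[const_idx] <- "constant"
    free_idx <- which(roles == "noise")
    info_idx <- if (spec$n_informative > 0) {
      sort(free_idx[sample.int(length(free_idx), spec$n_informative)])
    } else integer(0)
    roles[info_idx] <- "informative"

    bd <- spec$base_distribution
    meanlog <- runif(m, bd$meanlog_range[1], bd$meanlog_range[2])
    sdlog <- bd$sdlog
    shift_sign <- rep_len(c(1, -1), length(info_idx))

    logv <- matrix(rnorm(n * m, sd = sdlog), nrow = n, ncol = m)
    logv <- sweep(logv, 2, meanlog, `+`)
    if (length(info_idx) > 0 && spec$effect_size > 0) {
      late <- labels == "late"
      delta <- spec$effect_size * sdlog
      logv[late, info_idx] <- sweep(logv[late, info_idx, drop = FALSE], 2,
                                    shift_sign * delta, `+`)
    }
    values <- exp(logv)
    if (length(const_idx) > 0) {
      values[, const_idx] <- rep(exp(meanlog[const_idx]), each = n)
    }
    dimnames(values) <- list(sample_ids, feature_ids)
    expression_dataset(values, labels,
                       truth = feature_ids[info_idx],
                       constant_features = feature_ids[const_idx])
  })
}
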