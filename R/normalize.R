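#' Flag features that are constant on a training set
#'
#' A feature is flagged for removal iff it takes a single value across all
#' samples of the given training index set. The mask must then be applied
#' identically to train, validation and test partitions so the feature space
#' stays consistent within a fold.
#'
#' @param values samples-by-features numeric matrix.
#' @param train_index integer indices of the training samples.
#' @return named logical vector, `TRUE` where the feature is constant (to be
#'   removed).
#' @export
remove_constant_features <- function(values, train_index) {
  if (length(train_index) == 0L) {
    stop_config("training index set is empty")
  }
  sub <- values[train_index, , drop = FALSE]
  mask <- apply(sub, 2, function(x) all(x == x[1]))
  names(mask) <- colnames(values)
  mask
}

new_norm_params <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "NormalizationParams")
}

#' Fit and apply z-score normalization
#'
#' `fit_zscore()` computes per-feature mean and population standard deviation
#' (n denominator) from the training partition; `apply_zscore()` standardizes
#' any partition with those training statistics, so validation and test data
#' never contribute to the parameters.
#'
#' @param values samples-by-features numeric matrix (training data for
#'   `fit_zscore()`).
#' @param params a `NormalizationParams` from `fit_zscore()`.
#' @return `fit_zscore()`: `NormalizationParams` with `mu` and `sigma`;
#'   `apply_zscore()`: the transformed matrix.
#' @export
fit_zscore <- function(values) {
  mu <- colMeans(values)
  sigma <- sqrt(colMeans(values^2) - mu^2)
  # guard tiny negative rounding before sqrt-ed zero comparison
  sigma[!is.finite(sigma)] <- 0
  if (any(sigma == 0)) {
    stop_config("feature(s) with zero variance: %s — remove constant features first",
                paste(head(colnames(values)[sigma == 0], 5), collapse = ", "))
  }
  new_norm_params("zscore", mu = mu, sigma = sigma)
}

#' @rdname fit_zscore
#' @export
apply_zscore <- function(values, params) {
  stopifnot(inherits(params, "NormalizationParams"), params$kind == "zscore")
  sweep(sweep(values, 2, params$mu, `-`), 2, params$sigma, `/`)
}

#' Fit and apply min--max scaling to the unit interval
#'
#' `fit_minmax()` records the per-feature training minimum and maximum;
#' `apply_minmax()` maps values through `(x - Min) / (Max - Min)` and clips
#' the result to `[0, 1]`, so validation/test values outside the training
#' range stay inside the discretization bins used downstream.
#'
#' @inheritParams fit_zscore
#' @return `fit_minmax()`: `NormalizationParams` with `min` and `max`;
#'   `apply_minmax()`: the transformed matrix in `[0, 1]`.
#' @export
fit_minmax <- function(values) {
  mn <- apply(values, 2, min)
  mx <- apply(values, 2, max)
  if (any(mx == mn)) {
    stop_config("feature(s) with Max = Min: %s — remove constant features first",
                paste(head(colnames(values)[mx == mn], 5), collapse = ", "))
  }
  new_norm_params("minmax", min = mn, max = mx)
}

#' @rdname fit_minmax
#' @export
apply_minmax <- function(values, params) {
  stopifnot(inherits(params, "NormalizationParams"), params$kind == "minmax")
  out <- sweep(sweep(values, 2, params$min, `-`), 2,
               params$max - params$min, `/`)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
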