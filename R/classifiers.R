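# Classifier registry: each entry is list(fit = function(x, y) -> model,
# predict = function(model, x) -> list(class = factor, score = numeric))
# where score is oriented so larger means more "late"-like. Hyperparameters
# stay at library defaults unless noted.
.registry <- new.env(parent = emptyenv())

#' Register a classifier
#'
#' Adds (or replaces) an entry in the classifier registry used by
#' [evaluate_suite()]. This is also the plug-in slot for external scorers
#' such as a deep self-organizing auto-encoder: any pair of fit/predict
#' closures with the documented contract participates in the suite on equal
#' terms.
#'
#' @param name registry key.
#' @param fit function `(x, y)` returning a fitted model, where `x` is a
#'   numeric samples-by-features matrix and `y` a factor with levels
#'   `early`, `late`.
#' @param predict function `(model, x)` returning
#'   `list(class = factor, score = numeric)` with scores oriented toward the
#'   `late` class.
#' @return `name`, invisibly.
#' @export
register_classifier <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict), envir = .registry)
  invisible(name)
}

#' List registered classifier names
#' @return character vector.
#' @export
list_classifiers <- function() sort(ls(.registry))

get_classifier <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE)) {
    stop_config("unknown classifier '%s'; registered: %s",
                name, paste(list_classifiers(), collapse = ", "))
  }
  get(name, envir = .registry, inherits = FALSE)
}

score_to_class <- function(score, threshold = 0.5) {
  factor(ifelse(score > threshold, "late", "early"),
         levels = c("early", "late"))
}

register_builtin_classifiers <- function() {
  register_classifier("svm",
    fit = function(x, y) e1071::svm(x, y, kernel = "radial", scale = FALSE),
    predict = function(model, x) {
      pr <- predict(model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- if (colnames(dv)[1] == "early/late") -dv[, 1] else dv[, 1]
      list(class = factor(as.character(pr), levels = c("early", "late")),
           score = unname(score))
    })
  register_classifier("rf",
    fit = function(x, y) randomForest::randomForest(x, y),
    predict = function(model, x) {
      prob <- predict(model, x, type = "prob")[, "late"]
      list(class = score_to_class(prob), score = unname(prob))
    })
  register_classifier("knn",
    fit = function(x, y) list(x = x, y = y, k = 5L),
    predict = function(model, x) {
      pr <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
      win <- attr(pr, "prob")
      score <- ifelse(pr == "late", win, 1 - win)
      list(class = factor(as.character(pr), levels = c("early", "late")),
           score = unname(score))
    })
  register_classifier("nb",
    fit = function(x, y) e1071::naiveBayes(x, y),
    predict = function(model, x) {
      prob <- predict(model, x, type = "raw")[, "late"]
      list(class = score_to_class(prob), score = unname(prob))
    })
  register_classifier("lr",
    fit = function(x, y) {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- as.integer(y == "late")
      # separation warnings are expected when p is large relative to n
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    predict = function(model, x) {
      prob <- suppressWarnings(
        predict(model, newdata = data.frame(x, check.names = FALSE),
                type = "response"))
      list(class = score_to_class(prob), score = unname(prob))
    })
  register_classifier("xgboost",
    fit = function(x, y) {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "late"),
                                     nthread = 1L)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       nthread = 1L),
                         data = dtrain, nrounds = 50L, verbose = 0)
    },
    predict = function(model, x) {
      prob <- predict(model, xgboost::xgb.DMatrix(x, nthread = 1L))
      list(class = score_to_class(prob), score = unname(prob))
    })
}

.onLoad <- function(libname, pkgname) {
  register_builtin_classifiers()
}
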