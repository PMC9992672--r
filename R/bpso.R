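#' Binary PSO parameter block
#'
#' Defaults follow the published configuration: acceleration coefficients
#' `alpha = beta = 2` (global- and personal-best pulls), inertia
#' `theta = 0.9`, 35 particles and 100 iterations. `v_max = 6` clamps
#' velocities so the sigmoid transfer stays in (0.0025, 0.9975) and bits
#' remain flippable.
#'
#' @param alpha,beta acceleration coefficients (non-negative).
#' @param theta inertia weight in `[0, 1]`.
#' @param n_particles swarm size.
#' @param n_iterations number of swarm updates (0 returns the best of the
#'   random initial swarm).
#' @param v_max velocity clamp (positive).
#' @return a validated list of class `bpso_params`.
#' @export
bpso_params <- function(alpha = 2, beta = 2, theta = 0.9,
                        n_particles = 35L, n_iterations = 100L, v_max = 6) {
  p <- list(alpha = check_scalar_number(alpha, "alpha", lower = 0),
            beta = check_scalar_number(beta, "beta", lower = 0),
            theta = check_scalar_number(theta, "theta", lower = 0, upper = 1),
            n_particles = check_scalar_count(n_particles, "n_particles"),
            n_iterations = check_scalar_count(n_iterations, "n_iterations",
                                              minimum = 0L),
            v_max = check_scalar_number(v_max, "v_max", lower = 1e-8))
  structure(p, class = "bpso_params")
}

#' Sigmoid transfer function
#'
#' Maps a velocity element to the probability that the corresponding position
#' bit is set: `S(v) = 1 / (1 + exp(-v))`.
#'
#' @param v numeric vector of velocities.
#' @return probabilities in (0, 1), monotone in `v`.
#' @export
sigmoid_transfer <- function(v) plogis(v)

#' Velocity update
#'
#' `v' = theta * v + alpha * eps1 * (g_best - x) + beta * eps2 * (p_best - x)`,
#' then clamped element-wise to `[-v_max, v_max]`. `eps1` and `eps2` are
#' fresh uniform(0,1) vectors per call when not supplied.
#'
#' @param v current velocity vector.
#' @param x current binary position.
#' @param p_best personal-best position.
#' @param g_best global-best position.
#' @param theta,alpha,beta inertia and acceleration coefficients.
#' @param eps1,eps2 random vectors in `[0, 1]`; drawn from the current RNG
#'   stream when `NULL`.
#' @param v_max velocity clamp.
#' @return updated velocity vector.
#' @export
update_velocity <- function(v, x, p_best, g_best,
                            theta = 0.9, alpha = 2, beta = 2,
                            eps1 = NULL, eps2 = NULL, v_max = 6) {
  d <- length(v)
  if (length(x) != d || length(p_best) != d || length(g_best) != d) {
    stop_config("velocity/position vectors must share one length")
  }
  if (is.null(eps1)) eps1 <- runif(d)
  if (is.null(eps2)) eps2 <- runif(d)
  out <- theta * v + alpha * eps1 * (g_best - x) + beta * eps2 * (p_best - x)
  pmin(pmax(out, -v_max), v_max)
}

#' Stochastic binary position update
#'
#' Each bit is set to 1 with probability `S(v)` (independent uniform draw per
#' element from the current RNG stream).
#'
#' @param v velocity vector.
#' @return binary (0/1) position vector.
#' @export
update_position_binary <- function(v) {
  as.numeric(runif(length(v)) < sigmoid_transfer(v))
}

#' AUC-based fitness value
#'
#' `value = (1 - mean(aucs)) + sd(aucs)` with the sample standard deviation
#' (n - 1 denominator) of the per-validation-fold AUCs; a single fold
#' contributes zero dispersion. Minimized by the swarm; 0 iff every fold AUC
#' is 1.
#'
#' @param aucs numeric vector of per-inner-validation-fold AUCs.
#' @return list of class `FitnessValue` with `mean_auc`, `std_auc`, `value`.
#' @export
fitness_value <- function(aucs) {
  m <- mean(aucs)
  s <- if (length(aucs) > 1L) sd(aucs) else 0
  structure(list(mean_auc = m, std_auc = s, value = (1 - m) + s),
            class = "FitnessValue")
}

# Precompute the per-inner-fold z-scored design matrices for one outer fold,
# restricted to the candidate features. evaluate_fitness() then only subsets
# columns, which keeps the swarm's inner loop cheap.
#' Prepare per-inner-fold training data for fitness evaluation
#'
#' For one outer fold, builds the list of inner (train, validation) design
#' matrices restricted to the candidate features, z-scored with statistics
#' fitted on each inner training set.
#'
#' @param values samples-by-features raw matrix.
#' @param labels per-sample labels.
#' @param plan a [build_fold_plan()] result.
#' @param outer_index which outer fold.
#' @param candidate_features character vector of candidate feature ids.
#' @return list of per-inner-fold lists `(x_train, y_train, x_val, y_val)`.
#' @export
prepare_inner_data <- function(values, labels, plan, outer_index,
                               candidate_features) {
  stopifnot(inherits(plan, "FoldPlan"))
  missing <- setdiff(candidate_features, colnames(values))
  if (length(missing) > 0) {
    stop_config("unknown candidate feature(s): %s",
                paste(head(missing, 5), collapse = ", "))
  }
  fo <- plan$outer[[outer_index]]
  lapply(fo$inner, function(fi) {
    x <- values[, candidate_features, drop = FALSE]
    zs <- fit_zscore(x[fi$train, , drop = FALSE])
    list(x_train = apply_zscore(x[fi$train, , drop = FALSE], zs),
         y_train = factor(as.character(labels[fi$train]),
                          levels = c("early", "late")),
         x_val = apply_zscore(x[fi$validation, , drop = FALSE], zs),
         y_val = factor(as.character(labels[fi$validation]),
                        levels = c("early", "late")))
  })
}

svm_auc_scores <- function(x_train, y_train, x_val) {
  fit <- e1071::svm(x_train, y_train, kernel = "radial", scale = FALSE)
  dv <- attr(predict(fit, x_val, decision.values = TRUE), "decision.values")
  # libsvm orients the decision value toward the first label it encounters;
  # flip so larger scores always mean "late"
  if (colnames(dv)[1] == "early/late") -dv[, 1] else dv[, 1]
}

#' Evaluate the fitness of a feature subset
#'
#' Trains a radial-kernel SVM on each inner training fold restricted to the
#' selected features, scores each inner validation fold, and combines the
#' per-fold AUCs via [fitness_value()]. An empty subset returns the worst
#' fitness (2.0) instead of failing so the swarm can recover.
#'
#' @param position binary (0/1 or logical) vector over the candidate
#'   features.
#' @param inner_data the [prepare_inner_data()] result for this outer fold.
#' @return a `FitnessValue`.
#' @export
evaluate_fitness <- function(position, inner_data) {
  sel <- which(position > 0)
  if (length(sel) == 0L) {
    return(structure(list(mean_auc = NA_real_, std_auc = NA_real_, value = 2),
                     class = "FitnessValue"))
  }
  aucs <- vapply(inner_data, function(fd) {
    scores <- svm_auc_scores(fd$x_train[, sel, drop = FALSE], fd$y_train,
                             fd$x_val[, sel, drop = FALSE])
    auc_roc(scores, fd$y_val, positive = "late")
  }, 0)
  fitness_value(aucs)
}

#' Run binary particle swarm optimization over a candidate feature set
#'
#' Standard binary PSO: positions are bit vectors over the candidates,
#' initialized i.i.d. Bernoulli(0.5) with velocities uniform on
#' `[-1, 1]`; each iteration updates velocities toward the personal and
#' global bests, passes them through the sigmoid transfer, redraws bits, and
#' re-evaluates fitness. Fitness evaluations are memoized by bit pattern, so
#' revisited subsets cost nothing.
#'
#' @param inner_data per-inner-fold data from [prepare_inner_data()] (its
#'   column count fixes the search dimension), or any object accepted by a
#'   custom `fitness_fn`.
#' @param params a [bpso_params()] block.
#' @param seed integer seed driving initialization and all stochastic
#'   updates.
#' @param fitness_fn function `(position, inner_data) -> FitnessValue`;
#'   defaults to [evaluate_fitness()].
#' @param n_bits search dimension; defaults to the number of candidate
#'   columns in `inner_data`.
#' @return list with `best_position` (named 0/1 vector), `best_fitness`
#'   (a `FitnessValue`), and `trace` — the global-best fitness after
#'   initialization and after each iteration (length `n_iterations + 1`,
#'   non-increasing).
#' @export
run_bpso <- function(inner_data, params = bpso_params(), seed = 1L,
                     fitness_fn = evaluate_fitness, n_bits = NULL) {
  stopifnot(inherits(params, "bpso_params"))
  if (is.null(n_bits)) n_bits <- ncol(inner_data[[1]]$x_train)
  if (is.null(n_bits) || n_bits < 1L) {
    stop_config("candidate set is empty")
  }
  feature_names <- colnames(inner_data[[1]]$x_train) %||%
    paste0("bit", seq_len(n_bits))
  np <- params$n_particles
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(pos) {
    key <- paste(pos, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fitness_fn(pos, inner_data)
    cache[[key]] <- val
    val
  }
  with_seed(seed, {
    x <- matrix(as.numeric(runif(np * n_bits) < 0.5), nrow = np)
    v <- matrix(runif(np * n_bits, -1, 1), nrow = np)
    fit <- lapply(seq_len(np), function(i) eval_cached(x[i, ]))
    fval <- vapply(fit, `[[`, 0, "value")
    p_best <- x
    p_fit <- fit
    p_val <- fval
    g_idx <- which.min(fval)
    g_best <- x[g_idx, ]
    g_fit <- fit[[g_idx]]
    trace <- numeric(params$n_iterations + 1L)
    trace[1] <- g_fit$value
    if (params$n_iterations > 0) {
      for (t in seq_len(params$n_iterations)) {
        for (i in seq_len(np)) {
          v[i, ] <- update_velocity(v[i, ], x[i, ], p_best[i, ], g_best,
                                    theta = params$theta,
                                    alpha = params$alpha, beta = params$beta,
                                    v_max = params$v_max)
          x[i, ] <- update_position_binary(v[i, ])
          f <- eval_cached(x[i, ])
          if (f$value < p_val[i]) {
            p_best[i, ] <- x[i, ]
            p_fit[[i]] <- f
            p_val[i] <- f$value
          }
          if (f$value < g_fit$value) {
            g_best <- x[i, ]
            g_fit <- f
          }
        }
        trace[t + 1L] <- g_fit$value
      }
    }
    list(best_position = setNames(g_best, feature_names),
         best_fitness = g_fit,
         trace = trace)
  })
}

#' Consolidate per-outer-fold BPSO selections
#'
#' Unions the features switched on in any outer fold's global-best position
#' and reports, per feature, in how many outer folds it was selected.
#'
#' @param positions list of named 0/1 vectors (one global best per outer
#'   fold).
#' @return data.frame with `feature_id` and `outer_fold_frequency`, ordered
#'   by descending frequency then feature id.
#' @export
consolidate_selection <- function(positions) {
  if (length(positions) == 0L) stop_config("no positions to consolidate")
  sel <- lapply(positions, function(p) names(p)[p > 0])
  counts <- table(unlist(sel))
  out <- data.frame(feature_id = names(counts),
                    outer_fold_frequency = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$outer_fold_frequency, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
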