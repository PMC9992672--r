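test_that("metric battery matches direct evaluation of the formulas", {
  perfect <- compute_metrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1_positive, 1)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  m <- compute_metrics(c(TP = 40, FP = 15, TN = 35, FN = 10))
  expect_equal(m$accuracy, 75)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 70)
  expect_equal(m$f1_positive, 40 / (40 + 0.5 * 25), tolerance = 1e-9)
  expect_equal(m$mcc, (40 * 35 - 15 * 10) / sqrt(55 * 50 * 50 * 45),
               tolerance = 1e-9)
})

test_that("swapping the positive class swaps Sn and Sp only", {
  m <- compute_metrics(c(TP = 40, FP = 15, TN = 35, FN = 10))
  sw <- compute_metrics(c(TP = 35, FP = 10, TN = 40, FN = 15))
  expect_equal(sw$accuracy, m$accuracy)
  expect_equal(sw$mcc, m$mcc)
  expect_equal(sw$sensitivity, m$specificity)
  expect_equal(sw$specificity, m$sensitivity)
  expect_equal(sw$f1_positive, m$f1_negative)
})

test_that("degenerate confusion tables follow the documented conventions", {
  allpos <- compute_metrics(c(TP = 10, FP = 0, TN = 0, FN = 0))
  expect_equal(allpos$mcc, 0)  # zero-denominator convention
  expect_equal(allpos$accuracy, 100)
  expect_error(compute_metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("metrics agree with brute-force recomputation from labeled pairs", {
  set.seed(11)
  for (i in 1:25) {
    truth <- sample(c("early", "late"), 40, replace = TRUE)
    pred <- sample(c("early", "late"), 40, replace = TRUE)
    if (length(unique(truth)) < 2) next
    m <- compute_metrics(confusion_counts(truth, pred))
    orc <- oracle_metrics(truth, pred)
    expect_equal(m$accuracy, orc$accuracy, tolerance = 1e-9)
    expect_equal(m$mcc, orc$mcc, tolerance = 1e-9)
    expect_equal(m$f1_positive, orc$f1_positive, tolerance = 1e-9)
    expect_equal(m$sensitivity, orc$sensitivity, tolerance = 1e-9)
    expect_equal(m$specificity, orc$specificity, tolerance = 1e-9)
  }
})

test_that("AUC equals the pair-counting probability", {
  expect_equal(auc_roc(c(3, 4, 1, 2), c("late", "late", "early", "early")), 1)
  expect_equal(auc_roc(rep(1, 6), rep(c("early", "late"), 3)), 0.5)
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.2),
                       c("late", "early", "late", "early")), 0.75)
  set.seed(21)
  for (i in 1:20) {
    sc <- round(rnorm(30), 1)  # rounding forces ties
    lab <- sample(c("early", "late"), 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc_roc(sc, lab), oracle_auc_pairs(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(auc_roc(1:4, rep("late", 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  sc <- rnorm(40)
  lab <- sample(c("early", "late"), 40, replace = TRUE)
  base <- auc_roc(sc, lab)
  expect_equal(auc_roc(exp(sc), lab), base)
  expect_equal(auc_roc(rank(sc), lab), base)
  expect_equal(auc_roc(2 * sc + 5, lab), base)
})

test_that("unknown classifiers are rejected with the registry listed", {
  expect_error(get_classifier("nope"), "svm")
  expect_true(all(c("svm", "rf", "knn", "nb", "lr", "xgboost") %in%
                    list_classifiers()))
})

test_that("a label-revealing feature is classified perfectly by the suite", {
  set.seed(5)
  n <- 48
  labels <- rep(c("early", "late"), each = n / 2)
  vals <- matrix(exp(rnorm(n * 4)), n, 4,
                 dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:4)))
  vals[, 1] <- ifelse(labels == "late", 100, 1)
  d <- expression_dataset(vals, labels)
  plan <- build_fold_plan(d$labels, 3, 2, seed = 1)
  rep_ <- evaluate_suite(d, "f1", plan, seed = 1)
  test_rows <- rep_[rep_$split == "test", ]
  expect_true(all(test_rows$accuracy == 100))
  expect_true(all(test_rows$auc_roc == 1))
})

test_that("the report carries the seven metric columns in table order", {
  d <- toy_dataset(n_per_class = 12, n_features = 5, seed = 8)
  plan <- build_fold_plan(d$labels, 2, 2, seed = 1)
  rep_ <- evaluate_suite(d, d$feature_ids, plan, classifiers = c("svm", "nb"),
                         seed = 1)
  expect_equal(names(rep_), c("classifier", "split", "accuracy", "auc_roc",
                              "f1_early", "f1_late", "mcc", "sn", "sp"))
  expect_setequal(unique(rep_$split), c("train", "validation", "test"))
  expect_equal(nrow(rep_), 6)
  f <- tempfile(fileext = ".csv")
  write_metrics_report(rep_, f)
  back <- read.csv(f)
  expect_equal(back$accuracy, rep_$accuracy, tolerance = 1e-12)
})

test_that("a user-registered scorer plugs into the suite", {
  register_classifier("rowmean",
    fit = function(x, y) NULL,
    predict = function(model, x) {
      s <- rowMeans(x)
      list(class = factor(ifelse(s > 0, "late", "early"),
                          levels = c("early", "late")),
           score = s)
    })
  on.exit(rm("rowmean", envir = stageminer:::.registry))
  d <- toy_dataset(n_per_class = 12, n_features = 5, seed = 9)
  plan <- build_fold_plan(d$labels, 2, 2, seed = 1)
  rep_ <- evaluate_suite(d, d$feature_ids, plan, classifiers = "rowmean")
  expect_equal(unique(rep_$classifier), "rowmean")
})

test_that("concatenating feature sets keeps a memorizer's training fit", {
  d <- generate_dataset(synthetic_spec(20, 20, 30, n_informative = 4,
                                       effect_size = 2.5, seed = 12))
  plan <- build_fold_plan(d$labels, 2, 2, seed = 2)
  informative <- d$truth
  extra <- setdiff(d$feature_ids, d$truth)[1:10]
  base_rep <- evaluate_suite(d, informative, plan, classifiers = "rf",
                             seed = 3)
  both_rep <- evaluate_suite(d, c(informative, extra), plan,
                             classifiers = "rf", seed = 3)
  base_train <- base_rep$accuracy[base_rep$split == "train"]
  both_train <- both_rep$accuracy[both_rep$split == "train"]
  expect_gte(both_train, base_train - 1e-9)
})
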