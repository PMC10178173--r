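test_that("stratified folds are balanced, seeded and validated", {
  y <- rep(c("a", "b"), each = 20)
  f <- stratified_folds(y, n_folds = 10, seed = 1)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == "a"), 2L)
    expect_equal(sum(f == k & y == "b"), 2L)
  }
  expect_identical(f, stratified_folds(y, n_folds = 10, seed = 1))
  expect_false(identical(f, stratified_folds(y, n_folds = 10, seed = 2)))
  # the balanced 700-per-class layout gives exactly 70 per class per fold
  y700 <- rep(c("normal", "pesplanus"), each = 700)
  f700 <- stratified_folds(y700, n_folds = 10, seed = 3)
  expect_true(all(table(f700, y700) == 70L))
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 20)), 10), "at least")
})

test_that("metrics from pooled confusion counts follow the standard formulas", {
  expect_equal(unname(metrics_from_confusion(
    confusion_counts(100, 100, 0, 0))), rep(1, 4))
  m <- metrics_from_confusion(confusion_counts(TP = 1, TN = 0, FP = 1,
                                               FN = 0))
  expect_equal(unname(m), c(0.5, 0.5, 1, 2 / 3))
  # published precision/recall pair reproduces the published F1 to its
  # printed precision (the pair itself is printed rounded)
  expect_lt(abs(100 * f1_score(0.9365, 0.9686) - 95.22), 0.01)
  # F1 is the harmonic mean of precision and recall
  m2 <- metrics_from_confusion(confusion_counts(30, 50, 10, 7))
  expect_equal(m2[["f1"]],
               2 / (1 / m2[["precision"]] + 1 / m2[["recall"]]))
  expect_warning(metrics_from_confusion(confusion_counts(0, 5, 0, 1)),
                 "precision")
  expect_error(metrics_from_confusion(confusion_counts(0, 0, 0, 0)),
               "all-zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("cv_svm_loss is zero on wide-margin blobs and scale-covariant", {
  g <- generate_feature_matrix(feature_spec(50, D = 4, q = 4, delta = 6,
                                            seed = 1))
  X <- g$features$values
  y <- g$features$labels
  folds <- stratified_folds(y, n_folds = 10, seed = 1)
  expect_equal(cv_svm_loss(X, y, folds = folds), 0)
  # duplicating every column leaves the auto-scaled kernel unchanged
  g2 <- generate_feature_matrix(feature_spec(30, D = 5, q = 2, delta = 1,
                                             seed = 2))
  X2 <- g2$features$values
  y2 <- g2$features$labels
  f2 <- stratified_folds(y2, n_folds = 5, seed = 2)
  expect_equal(cv_svm_loss(X2, y2, folds = f2),
               cv_svm_loss(cbind(X2, X2), y2, folds = f2))
  expect_error(cv_svm_loss(cbind(c(1, Inf, 3, 4)), c("a", "a", "b", "b"),
                           folds = c(1, 2, 1, 2)), "finite")
})

test_that("the cubic SVM is calibrated at chance on permuted labels", {
  losses <- vapply(1:100, function(s) {
    g <- generate_feature_matrix(feature_spec(100, D = 10, q = 5,
                                              delta = 1.5, seed = s))
    yperm <- withr::with_seed(1000 + s, sample(g$features$labels))
    folds <- stratified_folds(yperm, n_folds = 10, seed = s)
    cv_svm_loss(g$features$values, yperm, folds = folds)
  }, numeric(1))
  expect_lt(abs(mean(losses) - 0.5), 0.07)
})

test_that("evaluate pools held-out predictions into a consistent report", {
  g <- generate_feature_matrix(feature_spec(40, D = 6, q = 3, delta = 4,
                                            seed = 3))
  rep1 <- evaluate(g$features, n_folds = 10, seed = 5)
  cts <- rep1$counts
  expect_equal(cts$TP + cts$TN + cts$FP + cts$FN, 80L)
  expect_equal(rep1$metrics, metrics_from_confusion(cts))
  expect_equal(rep1$positive_class, "normal")
  # every case held out exactly once
  expect_equal(sort(unique(rep1$fold_assignments)), 1:10)
  expect_equal(length(rep1$fold_assignments), 80L)
  # identical seed -> bit-identical report; accuracy complements cv loss
  rep2 <- evaluate(g$features, n_folds = 10, seed = 5)
  expect_identical(rep1, rep2)
  folds <- stratified_folds(g$features$labels, n_folds = 10, seed = 5)
  expect_equal(rep1$metrics[["accuracy"]],
               1 - cv_svm_loss(g$features, folds = folds))
  # wide margin: perfect scenario
  expect_equal(unname(rep1$metrics), rep(1, 4))
})

test_that("evaluation is near chance when the effect size is zero", {
  accs <- vapply(1:50, function(s) {
    g <- generate_feature_matrix(feature_spec(30, D = 8, q = 0, delta = 0,
                                              seed = 200 + s))
    evaluate(g$features, n_folds = 10, seed = s)$metrics[["accuracy"]]
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-9)
})

test_that("grid_benchmark tabulates accuracy per feature set and classifier", {
  g <- generate_feature_matrix(feature_spec(25, D = 5, q = 3, delta = 3,
                                            seed = 4))
  sets <- list(all = g$features)
  tab1 <- grid_benchmark(sets, list(cubic_svm = classifier_cubic_svm()),
                         n_folds = 5, seed = 9)
  expect_equal(dim(tab1), c(1L, 1L))
  # cell agrees with a standalone evaluation under the same seed
  ev <- evaluate(g$features, n_folds = 5, seed = 9)
  expect_equal(tab1["all", "cubic_svm"], ev$metrics[["accuracy"]])
  # adding a classifier adds a column without changing existing cells
  centroid <- function(Xtr, ytr, Xte) {
    mu <- lapply(split(seq_along(ytr), ytr), function(i)
      colMeans(Xtr[i, , drop = FALSE]))
    cls <- names(mu)
    cls[apply(Xte, 1, function(x)
      which.min(vapply(mu, function(m) sum((x - m)^2), numeric(1))))]
  }
  tab2 <- grid_benchmark(sets, list(cubic_svm = classifier_cubic_svm(),
                                    centroid = centroid),
                         n_folds = 5, seed = 9)
  expect_equal(tab2[["cubic_svm"]], tab1[["cubic_svm"]])
  expect_equal(ncol(tab2), 2L)
  # evaluator failure yields NA cell with warning, run continues
  broken <- function(Xtr, ytr, Xte) stop("boom")
  expect_warning(tab3 <- grid_benchmark(
    sets, list(cubic_svm = classifier_cubic_svm(), broken = broken),
    n_folds = 5, seed = 9), "boom")
  expect_true(is.na(tab3[["broken"]]))
  expect_equal(tab3[["cubic_svm"]], tab1[["cubic_svm"]])
})

test_that("svm_config validates and stores the cubic defaults", {
  cfg <- svm_config()
  expect_equal(cfg$degree, 3L)
  expect_equal(cfg$cost, 1)
  expect_equal(cfg$kernel_scale, "auto")
  expect_true(cfg$standardize)
  expect_error(svm_config(cost = 0), "cost")
  expect_error(svm_config(kernel_scale = -2), "kernel_scale")
  expect_error(cv_svm_loss(matrix(1:4, 2), c("a", "a"),
                           folds = c(1, 2)), "one class")
})
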