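#' Cubic-kernel SVM configuration
#'
#' Defaults reproduce the pinned classifier: polynomial kernel of degree 3,
#' box constraint 1, automatic kernel scale, standardization on. The kernel
#' applied to standardized inputs is `((x/s)'(y/s) + 1)^degree` with scale
#' `s`; `"auto"` resolves `s` per training fold as the median pairwise
#' Euclidean distance among up to 1000 seeded-subsampled standardized
#' training rows.
#'
#' @param degree polynomial order (3 = cubic).
#' @param cost box constraint C (> 0).
#' @param kernel_scale `"auto"` or an explicit positive number.
#' @param standardize center/scale columns with training-fold statistics.
#' @return object of class `svm_config`.
#' @export
svm_config <- function(degree = 3L, cost = 1, kernel_scale = "auto",
                       standardize = TRUE) {
  if (cost <= 0) stop("cost must be > 0")
  if (is.numeric(kernel_scale) && kernel_scale <= 0)
    stop("kernel_scale must be positive")
  structure(list(degree = as.integer(degree), cost = cost,
                 kernel_scale = kernel_scale,
                 standardize = isTRUE(standardize)),
            class = "svm_config")
}

#' Stratified fold assignment
#'
#' Within each class, indices are shuffled with the seeded generator and
#' dealt round-robin over the folds, so per-class fold sizes differ by at
#' most one and the assignment is reproducible.
#'
#' @param y class labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..n_folds, one per case.
#' @export
stratified_folds <- function(y, n_folds = 10L, seed = 0L) {
  y <- factor(y)
  counts <- table(y)
  if (any(counts < n_folds))
    stop("every class needs at least n_folds = ", n_folds,
         " members; smallest has ", min(counts))
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Standardize columns by training statistics; zero-variance columns get
# unit scale so they pass through centered.
standardize_fit <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$mu, "-"), 2L, st$sd, "/")
}

# Median pairwise Euclidean distance of up to max_n seeded-subsampled rows.
resolve_kernel_scale <- function(Xtr, seed = 0L, max_n = 1000L) {
  n <- nrow(Xtr)
  if (n > max_n) {
    keep <- withr::with_seed(as.integer(seed), sample.int(n, max_n))
    Xtr <- Xtr[keep, , drop = FALSE]
  }
  s <- stats::median(stats::dist(Xtr))
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

fit_poly_svm <- function(Xtr, ytr, config, scale_seed = 0L) {
  ytr <- factor(ytr)
  if (nlevels(droplevels(ytr)) < 2L)
    stop("degenerate training fold: only one class present")
  st <- if (config$standardize) standardize_fit(Xtr) else
    list(mu = rep(0, ncol(Xtr)), sd = rep(1, ncol(Xtr)))
  Xs <- standardize_apply(Xtr, st)
  s <- if (identical(config$kernel_scale, "auto"))
    resolve_kernel_scale(Xs, seed = scale_seed) else config$kernel_scale
  fit <- e1071::svm(Xs, droplevels(ytr), kernel = "polynomial",
                    degree = config$degree, gamma = 1 / s^2, coef0 = 1,
                    cost = config$cost, scale = FALSE)
  list(fit = fit, st = st)
}

predict_poly_svm <- function(model, Xte) {
  as.character(predict(model$fit, standardize_apply(Xte, model$st)))
}

#' Cross-validated misclassification loss of the cubic SVM
#'
#' For each fold the classifier is trained on the remaining folds
#' (standardization statistics and the automatic kernel scale are resolved
#' on the training folds only) and predicts the held-out fold; the loss is
#' the pooled misclassification fraction over all held-out predictions.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param y class labels; defaults to the `feature_matrix` labels.
#' @param config an [svm_config()].
#' @param folds integer fold assignment from [stratified_folds()].
#' @return loss in [0, 1].
#' @export
cv_svm_loss <- function(X, y = NULL, config = svm_config(), folds) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  y <- as.character(y)
  wrong <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    model <- fit_poly_svm(X[!te, , drop = FALSE], y[!te], config,
                          scale_seed = f)
    pred <- predict_poly_svm(model, X[te, , drop = FALSE])
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / nrow(X)
}

#' Confusion counts container
#'
#' @param TP,TN,FP,FN non-negative integer counts. The positive class is
#'   the normal class by convention (configurable in [evaluate()]): TP =
#'   correctly classified normal cases, TN = correctly classified positive
#'   findings (e.g. pes planus), FP / FN their misclassified counterparts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts TP=%d TN=%d FP=%d FN=%d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics from pooled confusion counts
#'
#' Standard definitions: accuracy = (TP + TN) / (TP + TN + FP + FN),
#' precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 the
#' harmonic mean of precision and recall. Zero-denominator precision or
#' recall is defined as 0 with a warning.
#'
#' @param counts a `confusion_counts`.
#' @return named numeric vector `(accuracy, precision, recall, f1)`, all in
#'   [0, 1].
#' @export
metrics_from_confusion <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("all-zero confusion counts")
  acc <- (counts$TP + counts$TN) / tot
  prec <- if (counts$TP + counts$FP == 0) {
    warning("precision denominator is zero; defining precision = 0"); 0
  } else counts$TP / (counts$TP + counts$FP)
  rec <- if (counts$TP + counts$FN == 0) {
    warning("recall denominator is zero; defining recall = 0"); 0
  } else counts$TP / (counts$TP + counts$FN)
  f1 <- f1_score(prec, rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in [0, 1].
#' @return F1 score in [0, 1]; 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Cross-validated evaluation with pooled confusion counts
#'
#' Runs the cubic SVM under seeded stratified k-fold cross-validation;
#' every case is predicted exactly once while held out, predictions are
#' pooled into a single confusion matrix, and the metric suite is computed
#' from the pooled counts.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param y class labels; defaults to the `feature_matrix` labels.
#' @param config an [svm_config()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param positive_class label treated as positive (default `"normal"`
#'   when present, otherwise the first class level).
#' @return object of class `eval_report`: list with `counts`
#'   (`confusion_counts`), `metrics`, `fold_assignments`, `seed`,
#'   `positive_class`.
#' @export
evaluate <- function(X, y = NULL, config = svm_config(), n_folds = 10L,
                     seed = 0L, positive_class = NULL) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(positive_class))
    positive_class <- if ("normal" %in% y) "normal" else sort(unique(y))[1]
  folds <- stratified_folds(y, n_folds = n_folds, seed = seed)
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    model <- fit_poly_svm(X[!te, , drop = FALSE], y[!te], config,
                          scale_seed = f)
    pred[te] <- predict_poly_svm(model, X[te, , drop = FALSE])
  }
  pos <- y == positive_class
  counts <- confusion_counts(
    TP = sum(pos & pred == positive_class),
    TN = sum(!pos & pred != positive_class),
    FP = sum(!pos & pred == positive_class),
    FN = sum(pos & pred != positive_class))
  structure(list(counts = counts, metrics = metrics_from_confusion(counts),
                 fold_assignments = folds, seed = as.integer(seed),
                 positive_class = positive_class),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "<eval_report: accuracy %.4f, precision %.4f, recall %.4f, f1 %.4f ",
    "(positive = %s)>\n"), m["accuracy"], m["precision"], m["recall"],
    m["f1"], x$positive_class))
  invisible(x)
}

#' Backbone-features x classifier accuracy grid
#'
#' Evaluates every (feature set, classifier) pair under seeded stratified
#' cross-validation and tabulates pooled accuracy. Classifiers are
#' pluggable: each registry entry is a function
#' `(Xtrain, ytrain, Xtest) -> predicted labels`. Only the cubic SVM's
#' behavior is pinned by this package; see [classifier_cubic_svm()].
#'
#' @param feature_sets named list of `feature_matrix` objects (all with the
#'   same labels).
#' @param classifiers named list of classifier functions.
#' @param n_folds folds (default 10).
#' @param seed integer seed.
#' @return data frame: one row per feature set, one column per classifier,
#'   cells = pooled CV accuracy (`NA` when an evaluator failed, with a
#'   warning).
#' @export
grid_benchmark <- function(feature_sets, classifiers, n_folds = 10L,
                           seed = 0L) {
  stopifnot(length(feature_sets) > 0L, length(classifiers) > 0L)
  out <- matrix(NA_real_, length(feature_sets), length(classifiers),
                dimnames = list(names(feature_sets), names(classifiers)))
  for (fs in names(feature_sets)) {
    fm <- feature_sets[[fs]]
    folds <- stratified_folds(fm$labels, n_folds = n_folds, seed = seed)
    for (cl in names(classifiers)) {
      acc <- tryCatch({
        pred <- character(length(fm$labels))
        for (f in sort(unique(folds))) {
          te <- folds == f
          pred[te] <- classifiers[[cl]](
            fm$values[!te, , drop = FALSE], fm$labels[!te],
            fm$values[te, , drop = FALSE])
        }
        mean(pred == fm$labels)
      }, error = function(e) {
        warning("classifier '", cl, "' failed on feature set '", fs, "': ",
                conditionMessage(e))
        NA_real_
      })
      out[fs, cl] <- acc
    }
  }
  as.data.frame(out)
}

#' Cubic-SVM classifier for the grid runner
#'
#' @param config an [svm_config()].
#' @return function `(Xtrain, ytrain, Xtest) -> predicted labels` suitable
#'   for [grid_benchmark()].
#' @export
classifier_cubic_svm <- function(config = svm_config()) {
  function(Xtrain, ytrain, Xtest) {
    model <- fit_poly_svm(Xtrain, ytrain, config)
    predict_poly_svm(model, Xtest)
  }
}

#' Published reference benchmark accuracies
#'
#' Returns the reference accuracy tables distributed with the package for
#' the public two-class flatfoot radiograph dataset: `plain` holds
#' cross-validated accuracy (%) of features from the original image only,
#' per backbone x classifier; `pyramidal` holds the accuracy / recall /
#' precision / F1 (%) of the pyramidal pipeline per backbone. Useful as a
#' comparison point for grid runs.
#'
#' @return list of two data frames, `plain` and `pyramidal`.
#' @export
reference_benchmarks <- function() {
  plain <- utils::read.csv(system.file("extdata",
    "reference_benchmark_plain.csv", package = "pyrads"),
    check.names = FALSE)
  pyramidal <- utils::read.csv(system.file("extdata",
    "reference_benchmark_pyramidal.csv", package = "pyrads"),
    check.names = FALSE)
  list(plain = plain, pyramidal = pyramidal)
}
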