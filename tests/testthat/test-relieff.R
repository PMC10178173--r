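test_that("min-max normalization maps columns to [0,1] with degenerate rule", {
  X <- cbind(c(2, 4, 6), c(5, 5, 5), c(0, 0.5, 1))
  N <- minmax_normalize(X)
  expect_equal(N[, 1], c(0, 0.5, 1))
  expect_equal(N[, 2], c(0, 0, 0))       # constant column -> zeros
  expect_equal(N[, 3], c(0, 0.5, 1))     # already normalized: unchanged
  expect_error(minmax_normalize(cbind(c(1, NA))), "missing")
  fm <- feature_matrix(X, c("a", "a", "b"))
  expect_s3_class(minmax_normalize(fm), "feature_matrix")
})

test_that("per-feature diff follows the continuous and discrete rules", {
  expect_equal(relieff_diff(0.3, 0.3), 0)
  expect_equal(relieff_diff(0.2, 0.9), 0.7)
  expect_equal(relieff_diff(0.2, 0.9, mode = "discrete"), 1)
  expect_equal(relieff_diff(0.4, 0.4, mode = "discrete"), 0)
})

test_that("ReliefF weights match hand-enumerated toy cases", {
  # 4 instances, 2 features, k = 1: frozen from explicit enumeration of
  # all pairwise Manhattan distances and direct application of the update
  X <- rbind(c(0, 0), c(0.1, 0.9), c(1, 0.2), c(0.9, 1))
  y <- c("a", "a", "b", "b")
  r <- relieff_rank(X, y, k_neighbors = 1)
  expect_equal(r$weights, c(0.8, -0.7), tolerance = 1e-12)
  expect_equal(r$order, c(1L, 2L))
  expect_equal(unname(r$priors), c(0.5, 0.5))
  # perfect 0/1 class-encoding feature, balanced classes: weight exactly 1
  Xe <- cbind(c(0, 0, 1, 1))
  re <- relieff_rank(Xe, y, k_neighbors = 1)
  expect_equal(re$weights, 1, tolerance = 1e-12)
  # constant feature gets weight exactly 0
  rc <- relieff_rank(cbind(c(0, 0, 1, 1), 0.5), y, k_neighbors = 1)
  expect_equal(rc$weights[2], 0)
  expect_error(relieff_rank(X, rep("a", 4)), "two classes")
  expect_warning(relieff_rank(X, y, k_neighbors = 5), "clipped")
})

test_that("ReliefF matches the brute-force oracle on random problems", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(10:30, 1)
      D <- sample(2:8, 1)
      k <- sample(1:3, 1)
      X <- matrix(stats::runif(n * D), n, D)
      y <- sample(c("a", "b", "c")[1:sample(2:3, 1)], n, replace = TRUE)
    })
    if (min(table(y)) < 2) y[1:2] <- setdiff(c("a", "b"), y[1])[1]
    r <- suppressWarnings(relieff_rank(X, y, k_neighbors = k))
    expect_equal(r$weights, relieff_brute(X, y, k), tolerance = 1e-12)
  }
})

test_that("weights are invariant to row permutation when distances are distinct", {
  withr::with_seed(10, {
    X <- matrix(stats::runif(24 * 5), 24, 5)
    y <- rep(c("a", "b"), each = 12)
    perm <- sample.int(24)
  })
  r1 <- relieff_rank(X, y, k_neighbors = 3)
  r2 <- relieff_rank(X[perm, ], y[perm], k_neighbors = 3)
  expect_equal(r1$weights, r2$weights, tolerance = 1e-12)
})

test_that("weights lie in [-1,1] on normalized features and sort stably", {
  withr::with_seed(2, {
    X <- minmax_normalize(matrix(stats::rnorm(40 * 6), 40, 6))
    y <- rep(c("a", "b"), 20)
  })
  r <- relieff_rank(X, y, k_neighbors = 4)
  expect_true(all(r$weights >= -1 & r$weights <= 1))
  expect_true(all(diff(r$weights[r$order]) <= 0))
  expect_equal(sort(r$order), seq_len(6))
})

test_that("a larger class separation never lowers an informative weight", {
  med_weight <- function(delta) {
    ws <- vapply(1:11, function(s) {
      g <- generate_feature_matrix(feature_spec(20, D = 6, q = 1,
                                                delta = delta, seed = s))
      N <- minmax_normalize(g$features)
      relieff_rank(N)$weights[g$informative]
    }, numeric(1))
    stats::median(ws)
  }
  ms <- vapply(c(0.5, 1.5, 3), med_weight, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("iterative selection reproduces a brute-force prefix sweep", {
  g <- generate_feature_matrix(feature_spec(15, D = 3, q = 1, delta = 3,
                                            seed = 5))
  X <- g$features$values
  y <- g$features$labels
  ranked <- relieff_rank(minmax_normalize(X), y, k_neighbors = 3)
  folds <- stratified_folds(y, n_folds = 5, seed = 1)
  evaluator <- function(Xs, yy) cv_svm_loss(Xs, yy, folds = folds)
  sel <- iterative_select(X, y, ranked, evaluator)
  expect_equal(sel$prefix_sizes, 1:3)
  direct <- vapply(1:3, function(i)
    evaluator(X[, ranked$order[1:i], drop = FALSE], y), numeric(1))
  expect_equal(unname(sel$loss_curve), direct)
  expect_equal(sel$best_size, sel$prefix_sizes[which.min(direct)])
  expect_equal(sel$selected_columns, ranked$order[seq_len(sel$best_size)])
})

test_that("a single separating feature is selected with zero loss", {
  g <- generate_feature_matrix(feature_spec(30, D = 8, q = 1, delta = 10,
                                            seed = 2))
  X <- g$features$values
  y <- g$features$labels
  ranked <- relieff_rank(minmax_normalize(X), y, k_neighbors = 5)
  expect_equal(ranked$order[1], g$informative)
  folds <- stratified_folds(y, n_folds = 5, seed = 3)
  sel <- iterative_select(X, y, ranked,
                          function(Xs, yy) cv_svm_loss(Xs, yy, folds = folds))
  expect_equal(unname(sel$loss_curve[1]), 0)
  expect_equal(sel$best_size, 1L)   # first minimum wins ties
})

test_that("selection on pure noise is not better than its permutation null", {
  g <- generate_feature_matrix(feature_spec(30, D = 5, q = 0, delta = 0,
                                            seed = 7))
  X <- g$features$values
  y <- g$features$labels
  min_loss <- function(yy, seed) {
    ranked <- relieff_rank(minmax_normalize(X), yy, k_neighbors = 5)
    folds <- stratified_folds(yy, n_folds = 5, seed = seed)
    min(iterative_select(X, yy, ranked, function(Xs, l)
      cv_svm_loss(Xs, l, folds = folds))$loss_curve)
  }
  observed <- min_loss(y, seed = 1)
  null <- vapply(1:200, function(s) {
    yp <- withr::with_seed(s, sample(y))
    min_loss(yp, seed = 1)
  }, numeric(1))
  # observed min loss sits inside the bulk of the permutation null
  expect_gte(observed, stats::quantile(null, 0.01) - 1e-9)
  expect_lte(observed, stats::quantile(null, 0.99) + 1e-9)
})

test_that("prefix controls behave: step thinning, clipping, coverage check", {
  g <- generate_feature_matrix(feature_spec(15, D = 6, q = 2, delta = 2,
                                            seed = 9))
  X <- g$features$values
  y <- g$features$labels
  ranked <- relieff_rank(minmax_normalize(X), y, k_neighbors = 3)
  folds <- stratified_folds(y, n_folds = 3, seed = 2)
  ev <- function(Xs, yy) cv_svm_loss(Xs, yy, folds = folds)
  sel <- iterative_select(X, y, ranked, ev, step = 2)
  expect_equal(sel$prefix_sizes, c(2L, 4L, 6L))
  expect_warning(iterative_select(X, y, ranked, ev, max_prefix = 99),
                 "clipped")
  bad <- relieff_rank(minmax_normalize(X[, 1:3]), y, k_neighbors = 3)
  expect_error(iterative_select(X, y, bad, ev), "cover")
})
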