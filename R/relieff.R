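#' Min-max normalize feature columns to [0, 1]
#'
#' Each column is mapped by `(x - min) / (max - min)`. Constant columns,
#' where the denominator would be zero, map to all-zeros; they carry no
#' class information and end up with ReliefF weight exactly 0.
#'
#' @param X numeric matrix or `feature_matrix`.
#' @return object of the same kind with every column in [0, 1].
#' @export
minmax_normalize <- function(X) {
  fm <- inherits(X, "feature_matrix")
  vals <- if (fm) X$values else as.matrix(X)
  if (nrow(vals) == 0L) stop("cannot normalize an empty matrix")
  if (anyNA(vals)) stop("missing values are not allowed")
  mins <- apply(vals, 2L, min)
  maxs <- apply(vals, 2L, max)
  rng <- maxs - mins
  out <- sweep(vals, 2L, mins, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  if (fm) feature_matrix(out, X$labels, column_origin = X$column_origin)
  else out
}

#' Per-feature distance between two instances
#'
#' For continuous features (the default) the distance is the absolute
#' difference of the normalized values, lying in [0, 1]. In discrete mode
#' it is 0 when the values are equal and 1 otherwise.
#'
#' @param v1,v2 feature values (scalars or equal-length vectors), assumed
#'   normalized to [0, 1] in continuous mode.
#' @param mode `"continuous"` or `"discrete"`.
#' @return numeric distance(s) in [0, 1].
#' @export
relieff_diff <- function(v1, v2, mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  if (mode == "continuous") abs(v1 - v2) else as.numeric(v1 != v2)
}

#' ReliefF feature weighting
#'
#' Neighbor-based feature weights: for each instance R_i, its k nearest
#' hits (same class) and k nearest misses per other class C are found, and
#' every feature's weight is decreased by the average hit distance and
#' increased by the prior-weighted average miss distance,
#' \deqn{W_A \leftarrow W_A - \sum_j diff(A, R_i, H_j)/(m k) +
#'   \sum_{C \ne class(R_i)} \frac{P(C)}{1 - P(class(R_i))}
#'   \sum_j diff(A, R_i, M_j^C)/(m k).}
#' Every instance is used once as R_i, in row order (m = n), which makes
#' the weights deterministic. Neighbor distance is the Manhattan distance
#' over the normalized features; ties are broken by lower row index.
#' Features are expected min-max normalized, which bounds weights in
#' [-1, 1]. When a class has at most `k` members, k is clipped per class
#' (hits: class size - 1, misses: class size) with a warning, and the
#' update divides by the clipped count.
#'
#' @param X numeric matrix or `feature_matrix`, normalized to [0, 1].
#' @param y class labels (character or factor), length `nrow(X)`; at least
#'   two classes required.
#' @param k_neighbors number of nearest hits/misses per class (default 10).
#' @return object of class `ranked_features`: list with `weights`, `order`
#'   (column indices by non-increasing weight, stable), `priors` and
#'   `k_neighbors`.
#' @export
relieff_rank <- function(X, y = NULL, k_neighbors = 10L) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (nlevels(y) < 2L) stop("ReliefF requires at least two classes")
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  counts <- table(y)
  if (any(counts <= k_neighbors))
    warning("some class has <= k_neighbors members; k clipped per class")
  priors <- as.numeric(counts) / n
  names(priors) <- names(counts)

  Dm <- as.matrix(stats::dist(X, method = "manhattan"))
  cls_idx <- split(seq_len(n), y)
  W <- numeric(ncol(X))
  m <- n
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    # nearest hits: same class, excluding R_i itself
    hits_pool <- setdiff(cls_idx[[ci]], i)
    kh <- min(k_neighbors, length(hits_pool))
    if (kh > 0L) {
      hp <- hits_pool[order(Dm[i, hits_pool], hits_pool)][seq_len(kh)]
      hd <- abs(X[rep(i, kh), , drop = FALSE] - X[hp, , drop = FALSE])
      W <- W - colSums(hd) / (m * kh)
    }
    for (cm in names(cls_idx)) {
      if (cm == ci) next
      miss_pool <- cls_idx[[cm]]
      km <- min(k_neighbors, length(miss_pool))
      if (km == 0L) next
      mp <- miss_pool[order(Dm[i, miss_pool], miss_pool)][seq_len(km)]
      md <- abs(X[rep(i, km), , drop = FALSE] - X[mp, , drop = FALSE])
      wC <- priors[[cm]] / (1 - priors[[ci]])
      W <- W + wC * colSums(md) / (m * km)
    }
  }
  structure(list(weights = W,
                 order = order(-W, seq_along(W), method = "radix"),
                 priors = priors, k_neighbors = as.integer(k_neighbors)),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features: %d features, k = %d; top weight %.4g>\n",
              length(x$weights), x$k_neighbors, x$weights[x$order[1]]))
  invisible(x)
}

#' Iterative ranked-prefix feature selection
#'
#' Evaluates growing prefixes of a feature ranking with a loss function and
#' keeps the prefix minimizing the loss. With `step = 1` and
#' `max_prefix = ncol(X)` every prefix 1..D of the ranking is evaluated;
#' larger steps thin the sweep for desk-scale runs. On ties the smallest
#' prefix wins. Prefixes index the *original* (unnormalized) columns of
#' `X` through the ranking.
#'
#' @param X numeric matrix or `feature_matrix` (original feature scale).
#' @param y class labels; defaults to the `feature_matrix` labels.
#' @param ranked a `ranked_features` covering the columns of `X`.
#' @param evaluator function `(X_subset, y) -> loss in [0, 1]`; typically a
#'   cross-validated classifier loss such as [cv_svm_loss()] with fixed
#'   folds.
#' @param max_prefix largest prefix length to evaluate (default all
#'   columns; clipped with a warning if larger).
#' @param step spacing between evaluated prefix lengths (default 1).
#' @return object of class `selection_result`: list with `loss_curve`
#'   (named by prefix length), `best_size`, `selected_columns` and
#'   `prefix_sizes`.
#' @export
iterative_select <- function(X, y = NULL, ranked, evaluator,
                             max_prefix = NULL, step = 1L) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  D <- ncol(X)
  if (length(ranked$order) != D)
    stop("ranking does not cover the columns of X")
  if (step < 1L) stop("step must be a positive integer")
  if (is.null(max_prefix)) max_prefix <- D
  if (max_prefix > D) {
    warning("max_prefix clipped from ", max_prefix, " to ", D)
    max_prefix <- D
  }
  sizes <- seq(from = step, to = max_prefix, by = step)
  if (length(sizes) == 0L) stop("no prefix sizes to evaluate")
  losses <- vapply(sizes, function(s) {
    evaluator(X[, ranked$order[seq_len(s)], drop = FALSE], y)
  }, numeric(1))
  names(losses) <- sizes
  best <- sizes[which.min(losses)]   # which.min: first minimum on ties
  structure(list(loss_curve = losses, best_size = best,
                 selected_columns = ranked$order[seq_len(best)],
                 prefix_sizes = sizes),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result: %d prefixes evaluated; best size %d, loss %.4f>\n",
    length(x$loss_curve), x$best_size, min(x$loss_curve)))
  invisible(x)
}
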