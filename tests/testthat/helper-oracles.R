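# Independent oracles, kept deliberately naive: explicit loops, explicit
# distance matrices, direct transcription of the weight-update formula.

# Brute-force ReliefF: full pairwise Manhattan distance matrix, explicit
# neighbor sorting with ties broken by lower index, one update cycle per
# instance (m = n), per-class clipped k, miss terms weighted by
# P(C) / (1 - P(class(Ri))).
relieff_brute <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  p <- ncol(X)
  classes <- sort(unique(y))
  prior <- sapply(classes, function(cl) mean(y == cl))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(abs(X[i, ] - X[j, ]))
  W <- rep(0, p)
  m <- n
  for (i in seq_len(n)) {
    for (cl in classes) {
      pool <- setdiff(which(y == cl), i)
      if (cl == y[i]) {
        kk <- min(k, length(pool))
        if (kk == 0) next
        nb <- pool[order(D[i, pool], pool)][1:kk]
        for (a in seq_len(p)) for (j in nb)
          W[a] <- W[a] - abs(X[i, a] - X[j, a]) / (m * kk)
      } else {
        kk <- min(k, length(pool))
        if (kk == 0) next
        nb <- pool[order(D[i, pool], pool)][1:kk]
        wC <- prior[[cl]] / (1 - prior[[y[i]]])
        for (a in seq_len(p)) for (j in nb)
          W[a] <- W[a] + wC * abs(X[i, a] - X[j, a]) / (m * kk)
      }
    }
  }
  W
}

# Reassemble a row-major list of grid x grid patches into one image.
stitch_patches <- function(patches, grid) {
  s <- dim(patches[[1]])[1]
  out <- array(0, c(s * grid, s * grid, 3))
  k <- 1
  for (r in seq_len(grid)) for (c in seq_len(grid)) {
    out[(r - 1) * s + seq_len(s), (c - 1) * s + seq_len(s), ] <- patches[[k]]
    k <- k + 1
  }
  out
}

# Deterministic pseudo-random uint8 test image.
rand_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, {
    array(as.double(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))
  })
}

const_image <- function(h, w, value = 100) array(as.double(value), c(h, w, 3))

# Tiny balanced manifest of random images, for fast structural tests.
tiny_manifest <- function(n_per_class, side = 16, seed = 1,
                          classes = c("normal", "pesplanus")) {
  recs <- list()
  k <- 0
  for (cl in classes) for (j in seq_len(n_per_class)) {
    k <- k + 1
    recs[[k]] <- radiograph_record(rand_image(side, side, seed + k),
                                   label = cl,
                                   source_id = sprintf("%s_%03d", cl, j))
  }
  pyrads:::new_manifest(recs, classes = classes)
}
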