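#' Specification for synthetic phantom radiographs
#'
#' Phantoms are geometric cartoons of a weight-bearing lateral foot
#' radiograph: a dark noisy background with a bright bone-like polyline
#' whose inferior arc angle (the stand-in for the calcaneal inclination
#' angle) is drawn from a per-class Gaussian. The defaults put the class
#' means at 15 and 25 degrees (SD 3) on either side of the 18-degree
#' diagnostic boundary used for flatfoot, so the class rule is a threshold
#' on the arc angle. When the two class means straddle the boundary, draws
#' are truncated to their class's side of it, making the label exactly
#' recoverable from the generated angle; with equal means (a null
#' configuration) no truncation is applied and labels are independent of
#' the images.
#'
#' @param n_per_class phantoms per class.
#' @param side image side in pixels (default 512).
#' @param angle_means named numeric vector of per-class mean arc angles in
#'   degrees; names are the class labels.
#' @param angle_sd Gaussian SD of the arc angle (degrees).
#' @param noise_sd pixel-noise SD on the 0-255 scale.
#' @param angle_threshold diagnostic boundary (degrees) separating the
#'   classes (default 18).
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_per_class, side = 512L,
                         angle_means = c(pesplanus = 15, normal = 25),
                         angle_sd = 3, noise_sd = 8,
                         angle_threshold = 18, seed = 0L) {
  stopifnot(n_per_class >= 1, side >= 16, length(angle_means) == 2L,
            !is.null(names(angle_means)), angle_sd >= 0, noise_sd >= 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 side = as.integer(side), angle_means = angle_means,
                 angle_sd = angle_sd, noise_sd = noise_sd,
                 angle_threshold = angle_threshold,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Distance from every grid pixel to a segment (unit coordinates).
segment_mask <- function(xs, ys, p1, p2, thickness) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- ((xs - p1[1]) * vx + (ys - p1[2]) * vy) / max(len2, 1e-12)
  t[t < 0] <- 0; t[t > 1] <- 1
  dx <- xs - (p1[1] + t * vx)
  dy <- ys - (p1[2] + t * vy)
  sqrt(dx^2 + dy^2) <= thickness
}

# One phantom canvas (grayscale, no noise) for a given arc angle.
phantom_canvas <- function(side, angle_deg) {
  xs <- matrix(rep((seq_len(side) - 0.5) / side, each = side), side)
  ys <- matrix(rep((seq_len(side) - 0.5) / side, times = side), side)
  heel <- c(0.20, 0.80)
  th <- angle_deg * pi / 180
  apex <- heel + 0.38 * c(cos(th), -sin(th))
  toe <- c(0.82, 0.80)
  shank_top <- c(apex[1], 0.12)
  canvas <- matrix(22, side, side)
  segs <- list(list(heel, apex), list(apex, toe), list(apex, shank_top))
  for (s in segs) {
    m <- segment_mask(xs, ys, s[[1]], s[[2]], thickness = 0.030)
    canvas[m] <- 205
  }
  canvas
}

#' Generate a two-class phantom radiograph dataset
#'
#' Fully deterministic given the spec's seed. When `dir` is supplied the
#' images are also written as PNGs in the `root/<class>/*.png` layout that
#' [load_dataset()] reads.
#'
#' @param spec a [phantom_spec()].
#' @param dir optional output directory.
#' @return a `dataset_manifest`; each record's `meta$arc_angle` holds the
#'   drawn angle.
#' @export
generate_phantoms <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  classes <- names(spec$angle_means)
  thr <- spec$angle_threshold
  mseq <- spec$angle_means
  # truncate to the class side of the boundary only when the means
  # straddle it (signal configuration); a null configuration stays free
  straddle <- (min(mseq) < thr) && (max(mseq) >= thr) && (mseq[1] != mseq[2])
  records <- list()
  withr::with_seed(spec$seed, {
    for (cl in classes) {
      mu <- spec$angle_means[[cl]]
      below <- mu < thr
      for (j in seq_len(spec$n_per_class)) {
        ang <- stats::rnorm(1, mu, spec$angle_sd)
        if (straddle) {
          tries <- 0L
          while (((ang < thr) != below) && tries < 1000L) {
            ang <- stats::rnorm(1, mu, spec$angle_sd)
            tries <- tries + 1L
          }
          if ((ang < thr) != below) ang <- mu  # pathological SD fallback
        }
        canvas <- phantom_canvas(spec$side, ang)
        img <- array(0, c(spec$side, spec$side, 3L))
        for (ch in 1:3)
          img[, , ch] <- canvas +
            stats::rnorm(spec$side^2, 0, spec$noise_sd)
        rec <- radiograph_record(clip_uint8(img), label = cl,
                                 source_id = sprintf("phantom_%s_%03d", cl, j),
                                 meta = list(arc_angle = ang))
        records[[length(records) + 1L]] <- rec
      }
    }
  })
  m <- new_manifest(records, classes = classes)
  if (!is.null(dir)) save_dataset(m, dir)
  m
}

#' Specification for synthetic labeled feature matrices
#'
#' @param n_per_class rows per class.
#' @param D total number of features.
#' @param q number of informative features (0 <= q <= D).
#' @param delta standardized class-mean shift on informative features
#'   (>= 0); informative columns are Normal(+delta/2, 1) in one class and
#'   Normal(-delta/2, 1) in the other, noise columns Normal(0, 1).
#' @param seed integer seed.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(n_per_class, D, q, delta, seed = 0L) {
  stopifnot(n_per_class >= 1, D >= 1, q >= 0, q <= D, delta >= 0)
  structure(list(n_per_class = as.integer(n_per_class), D = as.integer(D),
                 q = as.integer(q), delta = delta, seed = as.integer(seed)),
            class = "feature_spec")
}

#' Generate a labeled feature matrix with known informative structure
#'
#' @param spec a [feature_spec()].
#' @return list with `features` (a `feature_matrix`, classes `"normal"`
#'   and `"pesplanus"`) and `informative` (the ground-truth informative
#'   column indices).
#' @export
generate_feature_matrix <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  n <- 2L * spec$n_per_class
  labels <- rep(c("normal", "pesplanus"), each = spec$n_per_class)
  sign <- ifelse(labels == "normal", +1, -1)
  withr::with_seed(spec$seed, {
    informative <- sort(sample.int(spec$D, spec$q))
    X <- matrix(stats::rnorm(n * spec$D), n, spec$D)
    for (j in informative) X[, j] <- X[, j] + sign * spec$delta / 2
  })
  list(features = feature_matrix(X, labels), informative = informative)
}
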