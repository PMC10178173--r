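#' Construct a backbone feature extractor
#'
#' An extractor wraps a frozen, deterministic image-to-vector map: the
#' image is bilinearly resized to the backbone's native input side,
#' channel-normalized, and forward-passed; the returned vector is the
#' backbone's pre-softmax class-score ("Logits") output, of fixed width
#' `output_dim` (1000 for ImageNet-pretrained networks).
#'
#' @param name backbone name.
#' @param input_side native input resolution (positive integer).
#' @param output_dim width of the returned score vector.
#' @param normalization list with numeric `mean` and `sd` (length 1 or 3),
#'   applied per channel to pixel values rescaled to [0, 1].
#' @param forward function taking the normalized `input_side` square array
#'   and returning a numeric vector of length `output_dim`.
#' @param accepts_any_size if `TRUE` the pre-inference resize is skipped and
#'   `forward` receives the normalized image at its native size (used by
#'   extractors that pool internally, such as the stub).
#' @return object of class `backbone_extractor`.
#' @export
backbone_extractor <- function(name, input_side, output_dim, normalization,
                               forward, accepts_any_size = FALSE) {
  stopifnot(is.function(forward), input_side >= 1, output_dim >= 1)
  structure(list(name = name, input_side = as.integer(input_side),
                 output_dim = as.integer(output_dim),
                 normalization = normalization, forward = forward,
                 accepts_any_size = isTRUE(accepts_any_size)),
            class = "backbone_extractor")
}

#' @export
print.backbone_extractor <- function(x, ...) {
  cat(sprintf("<backbone_extractor %s: input %d, output_dim %d>\n",
              x$name, x$input_side, x$output_dim))
  invisible(x)
}

#' Deterministic stub feature extractor
#'
#' A weight-free stand-in for a pretrained backbone, used in tests and
#' desk-scale simulations: the image is block-mean downsampled to a fixed
#' small grid, flattened, and multiplied by a seeded fixed Gaussian
#' projection matrix. It honours the full extractor contract (fixed output
#' width, determinism, sensitivity to the input) without any network
#' weights.
#'
#' @param output_dim number of features returned per image.
#' @param seed integer seed fixing the projection matrix.
#' @param grid side of the downsampling grid (default 12; the flattened
#'   input has `3 * grid^2` entries).
#' @return a `backbone_extractor` named `"stub"`.
#' @export
make_stub_extractor <- function(output_dim, seed = 0L, grid = 12L) {
  stopifnot(output_dim >= 1, grid >= 1)
  p <- 3L * grid * grid
  W <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(output_dim * p, sd = 1 / sqrt(p)), output_dim, p)
  })
  backbone_extractor(
    name = "stub", input_side = 4L * grid, output_dim = output_dim,
    normalization = list(mean = 0.5, sd = 0.5),
    forward = function(x)
      as.numeric(W %*% as.numeric(block_mean_pool(x, grid))),
    accepts_any_size = TRUE)
}

# Registry of named backbone factories. Only the stub ships with the
# package; pretrained networks can be plugged in via register_backbone().
.backbones <- new.env(parent = emptyenv())

#' Register a backbone factory under a name
#'
#' @param name registry key, e.g. `"mobilenet_v2"`.
#' @param factory function `(...) -> backbone_extractor`.
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = .backbones)
  invisible(name)
}

#' List registered backbone names
#' @return character vector.
#' @export
list_backbones <- function() sort(ls(.backbones))

#' Fetch a registered backbone extractor
#'
#' @param name registry key.
#' @param ... passed to the registered factory (for the built-in `"stub"`:
#'   `output_dim`, `seed`, `grid`).
#' @return a `backbone_extractor`.
#' @export
get_backbone <- function(name, ...) {
  if (!exists(name, envir = .backbones))
    stop("no backbone registered under '", name, "'; available: ",
         paste(list_backbones(), collapse = ", "),
         ". Pretrained networks must be registered with register_backbone().")
  get(name, envir = .backbones)(...)
}

#' Extract one feature vector from one image
#'
#' The image is bilinearly resized to the extractor's native side, its
#' pixels rescaled to [0, 1] and channel-normalized, then forward-passed.
#'
#' @param extractor a `backbone_extractor`.
#' @param image H x W x 3 array, values 0-255.
#' @return numeric vector of length `extractor$output_dim`.
#' @export
extract_image_features <- function(extractor, image) {
  stopifnot(inherits(extractor, "backbone_extractor"))
  stopifnot_image(image)
  d <- dim(image)
  if (!extractor$accepts_any_size &&
      (d[1] != extractor$input_side || d[2] != extractor$input_side))
    image <- resize_image(image, extractor$input_side)
  x <- image / 255
  nm <- extractor$normalization
  mu <- rep_len(nm$mean, 3L)
  sdv <- rep_len(nm$sd, 3L)
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - mu[ch]) / sdv[ch]
  out <- extractor$forward(x)
  if (length(out) != extractor$output_dim)
    stop("extractor '", extractor$name, "' returned ", length(out),
         " values, expected ", extractor$output_dim)
  as.numeric(out)
}

#' Concatenate per-pyramid-image features for one case
#'
#' Slot i of the output (columns `(i-1)*output_dim + 1 ... i*output_dim`)
#' holds the feature vector of pyramid image i, in pyramid order (original,
#' then the 2x2 patches, then the 4x4 patches). With a 1000-wide backbone
#' this yields the 21,000-dimensional case vector.
#'
#' @param extractor a `backbone_extractor`.
#' @param patchset a `patch_set`.
#' @return numeric vector of length `21 * output_dim`.
#' @export
concat_case_features <- function(extractor, patchset) {
  stopifnot(inherits(patchset, "patch_set"))
  unlist(lapply(patchset$images,
                function(im) extract_image_features(extractor, im)),
         use.names = FALSE)
}

#' Create a feature matrix container
#'
#' @param values n x D numeric matrix (no missing values).
#' @param labels character vector of per-row class tags, length n.
#' @param column_origin data frame with one row per column describing its
#'   provenance (`pyramid_slot`, `within_index`); built automatically when
#'   omitted.
#' @param output_dim per-slot feature width used to build `column_origin`
#'   when it is omitted.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, column_origin = NULL,
                           output_dim = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  if (length(labels) != nrow(values))
    stop("labels length must equal nrow(values)")
  if (is.null(column_origin)) {
    if (is.null(output_dim)) output_dim <- ncol(values)
    slots <- if (ncol(values) == 0L) integer(0) else
      rep(seq_len(max(1L, ncol(values) %/% output_dim)), each = output_dim)
    column_origin <- data.frame(
      pyramid_slot = slots[seq_len(ncol(values))],
      within_index = if (ncol(values) == 0L) integer(0) else
        rep(seq_len(output_dim), length.out = ncol(values)))
  }
  structure(list(values = values, labels = as.character(labels),
                 column_origin = column_origin),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d cases x %d features; classes %s>\n",
              nrow(x$values), ncol(x$values),
              paste(names(table(x$labels)), collapse = "/")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Extract features for every record of a manifest
#'
#' Each record's image is resized to `side`, expanded into its 21-image
#' pyramid (when `pyramidal = TRUE`) and mapped through the extractor; rows
#' follow manifest order and labels are carried through. With
#' `pyramidal = FALSE` only the resized original is used, giving
#' `output_dim` columns instead of `21 * output_dim`.
#'
#' @param extractor a `backbone_extractor`.
#' @param manifest a `dataset_manifest`.
#' @param side working resolution images are resized to (default 512).
#' @param pyramidal use the full pyramid (default) or the original only.
#' @return a `feature_matrix` with `length(manifest)` rows.
#' @export
extract_dataset <- function(extractor, manifest, side = 512L,
                            pyramidal = TRUE) {
  n <- length(manifest$records)
  n_slots <- if (pyramidal) 21L else 1L
  D <- n_slots * extractor$output_dim
  if (n == 0L) {
    warning("empty manifest; returning 0 x ", D, " feature matrix")
    return(feature_matrix(matrix(numeric(0), 0L, D), character(0),
                          output_dim = extractor$output_dim))
  }
  values <- matrix(NA_real_, n, D)
  for (i in seq_len(n)) {
    r <- manifest$records[[i]]
    fv <- tryCatch({
      img <- resize_image(r$image, side)
      if (pyramidal)
        concat_case_features(extractor, build_pyramid(img, r$source_id))
      else
        extract_image_features(extractor, img)
    }, error = function(e)
      stop("feature extraction failed for case '", r$source_id, "': ",
           conditionMessage(e)))
    values[i, ] <- fv
  }
  feature_matrix(values, manifest_labels(manifest),
                 output_dim = extractor$output_dim)
}

#' Write a feature matrix as a flat CSV
#'
#' Suitable for small matrices; columns are `label` then `f1 ... fD`.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  names(df) <- paste0("f", seq_len(ncol(fm$values)))
  df <- cbind(data.frame(label = fm$labels), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @param output_dim per-slot width used to rebuild column provenance.
#' @return a `feature_matrix`.
#' @export
read_feature_csv <- function(path, output_dim = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feature_matrix(as.matrix(df[, -1, drop = FALSE]), df$label,
                 output_dim = output_dim)
}
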