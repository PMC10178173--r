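#' Create a labeled radiograph record
#'
#' A record couples one image with its class label and provenance. Images are
#' stored as H x W x 3 arrays with unsigned-8-bit pixel values (0-255),
#' the convention used throughout the package.
#'
#' @param image H x W x 3 numeric array, values in 0-255.
#' @param label class tag (character scalar), e.g. `"normal"` or
#'   `"pesplanus"`.
#' @param source_id opaque identifier of the case (file path, synthetic id).
#' @param is_augmented logical; `TRUE` for synthetically generated records.
#' @param transform_log list of applied geometric operations, each a list
#'   with at least elements `op` and `params`. Must be empty when
#'   `is_augmented` is `FALSE`.
#' @param meta optional named list of extra per-case metadata.
#' @return an object of class `radiograph_record`.
#' @export
radiograph_record <- function(image, label, source_id,
                              is_augmented = FALSE, transform_log = list(),
                              meta = list()) {
  stopifnot_image(image)
  if (!is.character(label) || length(label) != 1L)
    stop("label must be a single character string")
  if (!is_augmented && length(transform_log) > 0L)
    stop("non-augmented records must have an empty transform_log")
  structure(
    list(image = image, label = label, source_id = as.character(source_id),
         is_augmented = isTRUE(is_augmented), transform_log = transform_log,
         meta = meta),
    class = "radiograph_record")
}

#' @export
print.radiograph_record <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<radiograph_record %s [%s] %dx%dx%d%s>\n", x$source_id,
              x$label, d[1], d[2], d[3],
              if (x$is_augmented) " augmented" else ""))
  invisible(x)
}

new_manifest <- function(records, classes = NULL) {
  structure(list(records = records, classes = classes),
            class = "dataset_manifest")
}

#' Class counts of a dataset manifest
#'
#' @param manifest a `dataset_manifest`.
#' @return named integer vector, one entry per class label (sorted by name).
#' @export
class_counts <- function(manifest) {
  labs <- vapply(manifest$records, function(r) r$label, character(1))
  lv <- sort(union(manifest$classes, labs))
  tab <- table(factor(labs, levels = lv))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<dataset_manifest: %d records; %s>\n", length(x$records),
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  invisible(x)
}

#' @export
length.dataset_manifest <- function(x) length(x$records)

manifest_labels <- function(manifest) {
  vapply(manifest$records, function(r) r$label, character(1))
}

#' Load a two-class image dataset from a class-per-subdirectory layout
#'
#' Expects `root_dir/<class_name>/*.{jpg,jpeg,png}` with exactly two class
#' subdirectories. Every decodable file becomes one record, labeled by its
#' subdirectory name; record order is lexicographic by file path so that
#' downstream fold assignment is reproducible. Undecodable files are skipped
#' with a warning and recorded in the `skip_report` attribute.
#'
#' @param root_dir directory containing exactly two class subdirectories.
#' @return a `dataset_manifest`; attribute `skip_report` holds a character
#'   vector of skipped file paths.
#' @export
load_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop("root_dir does not exist: ", root_dir)
  classes <- sort(list.dirs(root_dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) != 2L)
    stop("root_dir must contain exactly two class subdirectories, found ",
         length(classes))
  records <- list()
  skipped <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(root_dir, cl),
                             pattern = "\\.(jpg|jpeg|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      warning("class subdirectory '", cl, "' contains no images")
    for (f in files) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping undecodable file: ", f)
        skipped <- c(skipped, f)
        next
      }
      records[[length(records) + 1L]] <-
        radiograph_record(img, label = cl, source_id = f)
    }
  }
  m <- new_manifest(records, classes = classes)
  attr(m, "skip_report") <- skipped
  m
}

#' Read one image file as a uint8 H x W x 3 array
#'
#' Greyscale images are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path JPEG or PNG file.
#' @return H x W x 3 numeric array with values in 0-255.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  clip_uint8(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Write a uint8 H x W x 3 array to a PNG or JPEG file
#'
#' @param image H x W x 3 array, values 0-255.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot_image(image)
  EBImage::writeImage(as_ebimage(image), path)
  invisible(path)
}

#' Resize an image by direct bilinear stretch
#'
#' The image is stretched to `side` x `side` without preserving aspect
#' ratio, matching the fixed square input the pyramid stage expects.
#'
#' @param image H x W x 3 array, values 0-255.
#' @param side target side length (positive integer).
#' @return `side` x `side` x 3 array.
#' @export
resize_image <- function(image, side) {
  stopifnot_image(image)
  if (!is.numeric(side) || length(side) != 1L || side <= 0 ||
      side != round(side))
    stop("side must be a positive integer")
  d <- dim(image)
  if (d[1] == side && d[2] == side) return(image)
  out <- EBImage::resize(as_ebimage(image), w = side, h = side,
                         filter = "bilinear")
  from_ebimage(out)
}

#' Apply one geometric augmentation to a record
#'
#' Supported operations: `rotate` (params: `angle` in degrees, positive =
#' counterclockwise), `scale` (params: `factor`, isotropic; the scaled image
#' is center-cropped or zero-padded back to the original frame) and `mirror`
#' (horizontal flip; no params). Output size always equals input size. The
#' returned record has `is_augmented = TRUE` and its `transform_log`
#' extended, so any augmented image can be replayed from its source.
#'
#' @param record a `radiograph_record`.
#' @param op_name one of `"rotate"`, `"scale"`, `"mirror"`.
#' @param params named list of operation parameters.
#' @param rng_seed integer seed (kept in the log for provenance; the
#'   operations themselves are deterministic).
#' @return augmented `radiograph_record`.
#' @export
augment_geometric <- function(record, op_name, params = list(),
                              rng_seed = 0L) {
  if (!inherits(record, "radiograph_record")) stop("record required")
  op_name <- match.arg(op_name, c("rotate", "scale", "mirror"))
  img <- record$image
  d <- dim(img)
  out <- switch(op_name,
    rotate = {
      ang <- params$angle
      if (is.null(ang)) stop("rotate requires params$angle")
      if (ang == 0) img else {
        r <- EBImage::rotate(as_ebimage(img), angle = ang,
                             filter = "bilinear",
                             output.dim = c(d[2], d[1]), bg.col = "black")
        from_ebimage(r)
      }
    },
    scale = {
      f <- params$factor
      if (is.null(f) || f <= 0) stop("scale requires positive params$factor")
      if (f == 1) img else scale_to_frame(img, f)
    },
    mirror = img[, rev(seq_len(d[2])), , drop = FALSE]
  )
  entry <- list(op = op_name, params = params, rng_seed = as.integer(rng_seed))
  radiograph_record(clip_uint8(out), label = record$label,
                    source_id = record$source_id, is_augmented = TRUE,
                    transform_log = c(record$transform_log, list(entry)),
                    meta = record$meta)
}

# Isotropic rescale, then center crop (factor > 1) or center zero-pad
# (factor < 1) back to the original frame.
scale_to_frame <- function(image, factor) {
  d <- dim(image)
  nh <- max(1L, round(d[1] * factor))
  nw <- max(1L, round(d[2] * factor))
  r <- from_ebimage(EBImage::resize(as_ebimage(image), w = nw, h = nh,
                                    filter = "bilinear"))
  out <- array(0, d)
  if (nh >= d[1]) {
    r0 <- floor((nh - d[1]) / 2)
    c0 <- floor((nw - d[2]) / 2)
    out[, , ] <- r[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]
  } else {
    r0 <- floor((d[1] - nh) / 2)
    c0 <- floor((d[2] - nw) / 2)
    out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- r
  }
  out
}

#' Balance class sizes by seeded geometric augmentation
#'
#' Originals are all retained; each class is topped up to exactly
#' `target_per_class` records by cycling over its originals in order and
#' applying one randomly drawn operation (rotate, scale or mirror) per
#' generated record. Draws are made with a seeded generator so the
#' augmented set is fully reproducible.
#'
#' Default parameter ranges: rotation angle uniform in [-10, 10] degrees,
#' scale factor uniform in [0.9, 1.1], mirroring = horizontal flip.
#'
#' @param manifest a `dataset_manifest`.
#' @param target_per_class target record count per class; must be at least
#'   the current maximum class count (records are never dropped).
#' @param rng_seed integer seed.
#' @param rotate_range,scale_range numeric length-2 vectors bounding the
#'   drawn rotation angle (degrees) and scale factor.
#' @return a balanced `dataset_manifest` with `2 * target_per_class` records.
#' @export
balance_by_augmentation <- function(manifest, target_per_class, rng_seed = 0L,
                                    rotate_range = c(-10, 10),
                                    scale_range = c(0.9, 1.1)) {
  cc <- class_counts(manifest)
  if (target_per_class < max(cc))
    stop("target_per_class (", target_per_class,
         ") is below an existing class count (", max(cc),
         "); subsampling is not supported")
  labs <- manifest_labels(manifest)
  new_records <- manifest$records
  withr::with_seed(as.integer(rng_seed), {
    for (cl in names(cc)) {
      need <- target_per_class - cc[[cl]]
      if (need == 0L) next
      idx <- which(labs == cl)
      for (j in seq_len(need)) {
        src <- manifest$records[[idx[((j - 1L) %% length(idx)) + 1L]]]
        op <- sample(c("rotate", "scale", "mirror"), 1L)
        params <- switch(op,
          rotate = list(angle = stats::runif(1, rotate_range[1],
                                             rotate_range[2])),
          scale  = list(factor = stats::runif(1, scale_range[1],
                                              scale_range[2])),
          mirror = list())
        new_records[[length(new_records) + 1L]] <-
          augment_geometric(src, op, params, rng_seed = rng_seed)
      }
    }
  })
  new_manifest(new_records, classes = manifest$classes)
}

#' Save a manifest to disk in the class-per-subdirectory layout
#'
#' Writes every record's image as `<dir>/<label>/<basename>.png` plus a
#' `manifest.csv` with columns `path`, `label`, `is_augmented` and
#' `transform_log` (JSON).
#'
#' @param manifest a `dataset_manifest`.
#' @param dir output directory (created if needed).
#' @return path of the written manifest CSV, invisibly.
#' @export
save_dataset <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(manifest$records))
  for (i in seq_along(manifest$records)) {
    r <- manifest$records[[i]]
    cdir <- file.path(dir, r$label)
    dir.create(cdir, showWarnings = FALSE)
    path <- file.path(cdir, sprintf("case_%05d.png", i))
    write_image(r$image, path)
    rows[[i]] <- data.frame(
      path = path, label = r$label, is_augmented = r$is_augmented,
      transform_log = as.character(
        jsonlite::toJSON(r$transform_log, auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  csv <- file.path(dir, "manifest.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  invisible(csv)
}
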