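#' Tile an image into a non-overlapping grid of patches
#'
#' Splits an S x S x 3 image into `grid_n^2` pixel-exact crops of side
#' `S / grid_n`, returned in row-major order (top-left patch first, rows
#' before columns).
#'
#' @param image S x S x 3 array with S divisible by `grid_n`.
#' @param grid_n grid size per axis (positive integer).
#' @return list of `grid_n^2` arrays of size `(S/grid_n)` square.
#' @export
tile <- function(image, grid_n) {
  stopifnot_image(image)
  d <- dim(image)
  if (d[1] != d[2]) stop("tile() expects a square image")
  if (grid_n < 1 || grid_n != round(grid_n)) stop("grid_n must be a positive integer")
  if (d[1] %% grid_n != 0L)
    stop("image side ", d[1], " is not divisible by grid_n = ", grid_n)
  s <- d[1] %/% grid_n
  patches <- vector("list", grid_n * grid_n)
  k <- 1L
  for (r in seq_len(grid_n)) {
    for (c in seq_len(grid_n)) {
      patches[[k]] <- image[(r - 1L) * s + seq_len(s),
                            (c - 1L) * s + seq_len(s), , drop = FALSE]
      k <- k + 1L
    }
  }
  patches
}

#' Build the 21-image pyramid for one case
#'
#' Produces the ordered pyramid used for feature generation: the original
#' image first, then its 2 x 2 tiling (4 patches of side S/2) and its
#' 4 x 4 tiling (16 patches of side S/4), both row-major. At the standard
#' working resolution S = 512 the pyramid is 1 x 512 + 4 x 256 + 16 x 128.
#'
#' @param image square S x S x 3 array, S divisible by 4 (512 in the
#'   standard workflow).
#' @param case_id opaque case identifier carried along with the patches.
#' @return an object of class `patch_set`: list with `images` (21 arrays),
#'   `sizes` (S, S/2, S/4) and `case_id`.
#' @export
build_pyramid <- function(image, case_id = "case") {
  stopifnot_image(image)
  d <- dim(image)
  if (d[1] != d[2]) stop("build_pyramid() expects a square image")
  if (d[1] %% 4L != 0L)
    stop("image side must be divisible by 4, got ", d[1])
  images <- c(list(image), tile(image, 2L), tile(image, 4L))
  structure(list(images = images,
                 sizes = c(d[1], d[1] %/% 2L, d[1] %/% 4L),
                 case_id = as.character(case_id)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set %s: %d images, sides %s>\n", x$case_id,
              length(x$images), paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Export the patches of a pyramid as PNG files
#'
#' Debug helper; files are named `<case_id>_L<level>_<row>_<col>.png` with
#' level 1 = original, 2 = the 2x2 patches, 3 = the 4x4 patches.
#'
#' @param patchset a `patch_set`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
export_patches <- function(patchset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grids <- c(1L, 2L, 4L)
  paths <- character(0)
  k <- 1L
  for (level in 1:3) {
    g <- grids[level]
    for (r in seq_len(g)) for (c in seq_len(g)) {
      p <- file.path(dir, sprintf("%s_L%d_%d_%d.png", patchset$case_id,
                                  level, r, c))
      write_image(patchset$images[[k]], p)
      paths <- c(paths, p)
      k <- k + 1L
    }
  }
  invisible(paths)
}
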