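# Internal helpers shared across modules.

# Derive a per-stage seed from a master seed. Multiplication is done in
# double precision and reduced mod 2^31 - 1 so the result is always a valid
# 32-bit seed, whatever the master seed.
derive_seed <- function(seed, stage) {
  offsets <- c(prepare = 11L, extract = 23L, select = 37L, evaluate = 53L,
               grid = 71L, phantom = 89L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% (2^31 - 1))
}

stopifnot_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (any(dim(image)[1:2] < 1L)) stop("image must have H >= 1, W >= 1")
  invisible(image)
}

# uint8 H x W x 3 array  <->  EBImage Image (x = width first, values in [0,1])
as_ebimage <- function(image) {
  EBImage::Image(aperm(image, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

from_ebimage <- function(img) {
  a <- aperm(as.array(img), c(2L, 1L, 3L))
  a <- round(a * 255)
  a[a < 0] <- 0
  a[a > 255] <- 255
  storage.mode(a) <- "double"
  a
}

clip_uint8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Exact area-average pooling weights mapping n_in samples onto n_out bins;
# rows sum to 1. Valid for any n_in, n_out >= 1 (upsampling repeats).
pool_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  for (g in seq_len(n_out)) {
    lo <- (g - 1) * n_in / n_out
    hi <- g * n_in / n_out
    h <- seq_len(n_in)
    ov <- pmax(0, pmin(hi, h) - pmax(lo, h - 1))
    A[g, ] <- ov / (hi - lo)
  }
  A
}

# Area-average downsampling of an H x W x 3 image to grid x grid x 3.
block_mean_pool <- function(image, grid) {
  d <- dim(image)
  Ar <- pool_matrix(d[1], grid)
  Ac <- pool_matrix(d[2], grid)
  out <- array(0, c(grid, grid, 3L))
  for (ch in 1:3) out[, , ch] <- Ar %*% image[, , ch] %*% t(Ac)
  out
}
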