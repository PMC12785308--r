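# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Construct an RGB image
#'
#' The unit every pipeline stage consumes and produces: a height x width x 3
#' array of integer intensities in `[0, 255]`.
#'
#' @param data numeric array of dimension `c(height, width, 3)` with values in
#'   `[0, 255]`. Non-integer values are rounded half away from zero.
#' @return an integer array of class `rgb_image`.
#' @export
rgb_image <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop("`data` must be a height x width x 3 array", call. = FALSE)
  if (anyNA(data) || min(data) < 0 || max(data) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  out <- array(as.integer(round_half_up(data)), dim = dim(data))
  class(out) <- c("rgb_image", class(out))
  out
}

#' @rdname rgb_image
#' @param x object to test or coerce.
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

as_rgb_image <- function(x) if (is_rgb_image(x)) x else rgb_image(x)

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d>\n", d[1], d[2]))
  invisible(x)
}

#' Create a uniform image
#'
#' @param height,width dimensions in pixels.
#' @param color length-3 intensity triplet in `[0, 255]`.
#' @return an [rgb_image()].
#' @export
constant_image <- function(height, width, color = c(255, 255, 255)) {
  stopifnot(height >= 1, width >= 1, length(color) == 3)
  rgb_image(array(rep(color, each = height * width), dim = c(height, width, 3)))
}

#' Luma channel of an image
#'
#' Rec. 601 luma, `round(0.299 R + 0.587 G + 0.114 B)`, as an integer matrix.
#'
#' @param image an [rgb_image()].
#' @return height x width integer matrix.
#' @export
luma <- function(image) {
  image <- as_rgb_image(image)
  round_half_up(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Read and write images as PNG
#'
#' PNG is used throughout because it is lossless: byte-identity of outputs
#' under a fixed seed is part of the pipeline's reproducibility contract.
#'
#' @param path file path.
#' @return `read_image_png` returns an [rgb_image()]; `write_image_png`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 2L) arr <- array(rep(arr[, , 1], 3), dim = c(dim(arr)[1:2], 3))
  rgb_image(round_half_up(arr * 255))
}

#' @rdname read_image_png
#' @param image an [rgb_image()].
#' @export
write_image_png <- function(image, path) {
  image <- as_rgb_image(image)
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

# run code with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so generators are pure functions of (inputs, seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed and an identifier
#'
#' Stable integer hash of `(master, id)` so that per-image / per-matrix
#' sub-streams do not shift when items are added to a batch.
#'
#' @param master integer master seed.
#' @param id character identifier (e.g. an image id).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, id) {
  stopifnot(length(master) == 1, is.finite(master), length(id) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(master)) * 48271) %% m
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% m
  as.integer(h)
}
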