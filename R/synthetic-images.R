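#' Specification of a synthetic scalp-like image
#'
#' Describes a procedurally drawn stand-in for a trichoscopic field of view:
#' a skin-toned background crossed by dark curvilinear hair shafts, with
#' small dark follicular dots and optional larger colored patches emulating
#' scale or erythema. These are deliberately schematic - enough countable,
#' localized structure to test that the transformation pipeline preserves
#' diagnostic morphology, with no pretence of photorealism.
#'
#' @param height,width image dimensions in pixels (>= 64).
#' @param background_color skin-tone intensity triplet.
#' @param n_hairs number of hair-shaft strokes.
#' @param hair_thickness_range stroke thickness range, pixels (min, max).
#' @param hair_darkness_range how much darker than background a stroke is,
#'   intensity units (min, max).
#' @param n_follicular_dots number of filled follicular dots.
#' @param dot_radius_range dot radius range, pixels.
#' @param patch_specs list of `list(center = c(y, x), radius, color)` patches
#'   drawn beneath hairs and dots.
#' @return a list of class `image_spec`.
#' @export
image_spec <- function(height = 256, width = 256,
                       background_color = c(224, 196, 176),
                       n_hairs = 12,
                       hair_thickness_range = c(2, 4),
                       hair_darkness_range = c(80, 140),
                       n_follicular_dots = 8,
                       dot_radius_range = c(2, 4),
                       patch_specs = list()) {
  spec <- list(height = height, width = width,
               background_color = background_color, n_hairs = n_hairs,
               hair_thickness_range = hair_thickness_range,
               hair_darkness_range = hair_darkness_range,
               n_follicular_dots = n_follicular_dots,
               dot_radius_range = dot_radius_range, patch_specs = patch_specs)
  validate_image_spec(spec)
  class(spec) <- "image_spec"
  spec
}

validate_image_spec <- function(spec) {
  if (spec$height < 64 || spec$width < 64)
    stop("image dimensions must be >= 64 pixels", call. = FALSE)
  if (spec$n_hairs < 0 || spec$n_follicular_dots < 0)
    stop("structure counts must be >= 0", call. = FALSE)
  for (nm in c("hair_thickness_range", "hair_darkness_range", "dot_radius_range")) {
    r <- spec[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop(sprintf("`%s` must satisfy min <= max", nm), call. = FALSE)
  }
  if (any(spec$background_color < 0) || any(spec$background_color > 255))
    stop("colors must lie in [0, 255]", call. = FALSE)
  invisible(spec)
}

# stamp hard (non-anti-aliased) filled discs of radius `rad` at the given
# (y, x) centres into each channel; exact pixels keep brute-force oracles exact
stamp_discs <- function(arr, ys, xs, rad, color) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  r <- ceiling(rad)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= rad^2, , drop = FALSE]
  py <- outer(ys, off$dy, `+`); px <- outer(xs, off$dx, `+`)
  keep <- py >= 1 & py <= h & px >= 1 & px <= w
  idx <- cbind(c(py)[c(keep)], c(px)[c(keep)])
  idx <- idx[!duplicated(idx), , drop = FALSE]
  for (ch in 1:3) arr[cbind(idx, ch)] <- color[ch]
  arr
}

# dense point sampling of a quadratic Bezier curve through three control points
bezier_points <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  y <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  x <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(y, x)
}

#' Generate a synthetic scalp image with known ground truth
#'
#' Draws, on a uniform background: the configured patches (filled circles),
#' then `n_hairs` hair shafts as smooth quadratic curves stamped with hard
#' (non-anti-aliased) circular brushes, then `n_follicular_dots` filled dark
#' dots. Every drawn structure is returned as ground truth. The result is a
#' pure function of `(spec, seed)`: the same call always yields byte-identical
#' pixels.
#'
#' @param spec an [image_spec()].
#' @param seed integer seed.
#' @return a list with elements `image` (an [rgb_image()]) and `structures`
#'   (a data frame: type, y0, x0, y1, x1, y2, x2, size, darkness; curve
#'   control points for hairs, centre/radius for dots and patches).
#' @export
generate_scalp_image <- function(spec, seed) {
  validate_image_spec(spec)
  h <- spec$height; w <- spec$width
  arr <- array(rep(spec$background_color, each = h * w), dim = c(h, w, 3))
  structures <- list()
  with_seed(seed, {
    for (p in spec$patch_specs) {
      arr <- stamp_discs(arr, round(p$center[1]), round(p$center[2]), p$radius, p$color)
      structures[[length(structures) + 1]] <- data.frame(
        type = "patch", y0 = p$center[1], x0 = p$center[2], y1 = NA, x1 = NA,
        y2 = NA, x2 = NA, size = p$radius, darkness = NA)
    }
    if (spec$n_hairs > 0) for (i in seq_len(spec$n_hairs)) {
      p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      p2 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      mid <- (p0 + p2) / 2
      p1 <- mid + stats::rnorm(2, 0, max(h, w) / 8) # curvature control point
      thick <- stats::runif(1, spec$hair_thickness_range[1], spec$hair_thickness_range[2])
      dark <- stats::runif(1, spec$hair_darkness_range[1], spec$hair_darkness_range[2])
      color <- pmax(spec$background_color - dark, 0)
      pts <- bezier_points(p0, p1, p2, n = 4 * ceiling(sqrt(sum((p2 - p0)^2)) + 8))
      arr <- stamp_discs(arr, round(pts[, 1]), round(pts[, 2]), thick / 2, color)
      structures[[length(structures) + 1]] <- data.frame(
        type = "hair", y0 = p0[1], x0 = p0[2], y1 = p1[1], x1 = p1[2],
        y2 = p2[1], x2 = p2[2], size = thick, darkness = dark)
    }
    if (spec$n_follicular_dots > 0) for (i in seq_len(spec$n_follicular_dots)) {
      c0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      rad <- stats::runif(1, spec$dot_radius_range[1], spec$dot_radius_range[2])
      dark <- stats::runif(1, spec$hair_darkness_range[1], spec$hair_darkness_range[2])
      color <- pmax(spec$background_color - dark, 0)
      arr <- stamp_discs(arr, round(c0[1]), round(c0[2]), rad, color)
      structures[[length(structures) + 1]] <- data.frame(
        type = "dot", y0 = c0[1], x0 = c0[2], y1 = NA, x1 = NA, y2 = NA,
        x2 = NA, size = rad, darkness = dark)
    }
  })
  structures <- if (length(structures)) do.call(rbind, structures) else
    data.frame(type = character(), y0 = numeric(), x0 = numeric(),
               y1 = numeric(), x1 = numeric(), y2 = numeric(), x2 = numeric(),
               size = numeric(), darkness = numeric())
  list(image = rgb_image(arr), structures = structures)
}
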