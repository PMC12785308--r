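#' Configuration of the anti-leakage transformation pipeline
#'
#' Declares the parameter ranges of the ten-stage image transformation
#' sequence: border crop, white padding, random scaling, constrained
#' rotation, brightness/contrast/saturation/gamma adjustment, light Gaussian
#' blur, low-variance Gaussian noise, and a smoothed-noise perturbation.
#' The defaults are deliberately subtle: they disrupt low-level pixel
#' statistics that pretrained vision models can memorize while leaving
#' diagnostic morphology (hair shafts, follicular openings, scaling)
#' untouched for the human reader.
#'
#' @param crop_fraction_per_side fraction of each side removed by the border
#'   crop (default 0.0075, i.e. 0.75\% per side).
#' @param pad_fraction fraction of each (post-crop) side added as uniform
#'   padding (default 0.015).
#' @param pad_color padding and rotation-fill intensity triplet (default white).
#' @param scale_range multiplicative rescaling factor range (default 0.90-1.10).
#' @param rotation_range_deg rotation angle range in degrees (default -3 to 3).
#' @param brightness_range,contrast_range multiplicative factor ranges
#'   (default 1.01-1.04).
#' @param saturation_range chroma scaling factor range (default 1.005-1.01).
#' @param gamma_range gamma-correction exponent range (default 0.8-1.2).
#' @param blur_kernel odd Gaussian blur kernel size in pixels (default 3).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise,
#'   in intensity units (default 2.0).
#' @param perturb_amplitude maximum absolute value of the smoothed random
#'   perturbation field, intensity units (default 3.0).
#' @param perturb_smooth_sd Gaussian smoothing sd of the perturbation field,
#'   in pixels (default 8.0).
#' @return a list of class `transform_config`.
#' @export
transform_config <- function(crop_fraction_per_side = 0.0075,
                             pad_fraction = 0.015,
                             pad_color = c(255, 255, 255),
                             scale_range = c(0.90, 1.10),
                             rotation_range_deg = c(-3, 3),
                             brightness_range = c(1.01, 1.04),
                             contrast_range = c(1.01, 1.04),
                             saturation_range = c(1.005, 1.01),
                             gamma_range = c(0.8, 1.2),
                             blur_kernel = 3,
                             noise_sd = 2.0,
                             perturb_amplitude = 3.0,
                             perturb_smooth_sd = 8.0) {
  cfg <- list(crop_fraction_per_side = crop_fraction_per_side,
              pad_fraction = pad_fraction, pad_color = pad_color,
              scale_range = scale_range, rotation_range_deg = rotation_range_deg,
              brightness_range = brightness_range, contrast_range = contrast_range,
              saturation_range = saturation_range, gamma_range = gamma_range,
              blur_kernel = blur_kernel, noise_sd = noise_sd,
              perturb_amplitude = perturb_amplitude,
              perturb_smooth_sd = perturb_smooth_sd)
  validate_transform_config(cfg)
  class(cfg) <- "transform_config"
  cfg
}

validate_transform_config <- function(cfg) {
  chk_frac <- function(x, nm) if (x < 0 || x >= 0.25)
    stop(sprintf("`%s` must lie in [0, 0.25)", nm), call. = FALSE)
  chk_frac(cfg$crop_fraction_per_side, "crop_fraction_per_side")
  chk_frac(cfg$pad_fraction, "pad_fraction")
  for (nm in c("scale_range", "rotation_range_deg", "brightness_range",
               "contrast_range", "saturation_range", "gamma_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop(sprintf("`%s` must be a (min, max) pair with min <= max", nm), call. = FALSE)
  }
  if (cfg$blur_kernel < 1 || cfg$blur_kernel %% 2 != 1)
    stop("`blur_kernel` must be odd and >= 1", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$perturb_amplitude < 0 || cfg$perturb_smooth_sd < 0)
    stop("noise/perturbation parameters must be >= 0", call. = FALSE)
  if (any(cfg$pad_color < 0) || any(cfg$pad_color > 255) || length(cfg$pad_color) != 3)
    stop("`pad_color` must be an intensity triplet in [0, 255]", call. = FALSE)
  invisible(cfg)
}

#' Crop a fixed fraction from every border
#'
#' Removes `round(fraction * dimension)` pixels (rounding half away from
#' zero, per axis) from each of the four sides, eliminating border artifacts
#' such as ruler marks and vignetting.
#'
#' @param image an [rgb_image()].
#' @param fraction proportion of each side to remove.
#' @return the cropped [rgb_image()].
#' @export
crop_borders <- function(image, fraction) {
  image <- as_rgb_image(image)
  stopifnot(fraction >= 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  ny <- round_half_up(fraction * h); nx <- round_half_up(fraction * w)
  if (h - 2 * ny < 1 || w - 2 * nx < 1)
    stop("crop fraction would consume the whole image", call. = FALSE)
  rgb_image(unclass(image)[(ny + 1):(h - ny), (nx + 1):(w - nx), , drop = FALSE])
}

#' Add a uniform frame of padding
#'
#' Adds `round(fraction * dimension)` pixels of `color` on each side, per
#' axis; interior pixels are unchanged. Used to subtly shift the image
#' composition after the border crop.
#'
#' @inheritParams crop_borders
#' @param color padding intensity triplet.
#' @return the padded [rgb_image()].
#' @export
add_padding <- function(image, fraction, color = c(255, 255, 255)) {
  image <- as_rgb_image(image)
  stopifnot(fraction >= 0, length(color) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  ny <- round_half_up(fraction * h); nx <- round_half_up(fraction * w)
  if (ny == 0 && nx == 0) return(image)
  out <- array(rep(color, each = (h + 2 * ny) * (w + 2 * nx)),
               dim = c(h + 2 * ny, w + 2 * nx, 3))
  out[(ny + 1):(ny + h), (nx + 1):(nx + w), ] <- unclass(image)
  rgb_image(out)
}

#' Geometric stage: rescale then rotate
#'
#' Rescales by `scale` (bilinear; output dimensions are
#' `round(scale * dims)`), then rotates about the centre by `angle` degrees,
#' keeping the canvas size and filling exposed corners with `fill`. These
#' small geometric changes emulate plausible photographic variation without
#' disturbing lesion structure.
#'
#' @inheritParams crop_borders
#' @param scale rescaling factor in `(0, 4]`.
#' @param angle rotation angle in degrees.
#' @param fill fill triplet for regions rotated in from outside the frame.
#' @return the transformed [rgb_image()].
#' @export
geometric_stage <- function(image, scale, angle, fill = c(255, 255, 255)) {
  image <- as_rgb_image(image)
  if (!is.finite(scale) || scale <= 0 || scale > 4)
    stop("`scale` must lie in (0, 4]", call. = FALSE)
  stopifnot(is.finite(angle))
  arr <- unclass(image) * 1.0
  h <- dim(arr)[1]; w <- dim(arr)[2]
  if (scale != 1) {
    oh <- max(1, round_half_up(scale * h)); ow <- max(1, round_half_up(scale * w))
    arr <- resize_bilinear(arr, oh, ow)
  }
  if (angle != 0) arr <- rotate_fill(arr, angle, fill)
  rgb_image(clip8(round_half_up(arr)))
}

#' Photometric stage: brightness, contrast, saturation, gamma
#'
#' Applies, in order: brightness (multiply all channels), contrast (scale the
#' deviation from the per-image mean), saturation (scale chroma about the
#' per-pixel luma), and gamma correction
#' `v <- 255 * (v / 255)^(1 / gamma)`. Each step clips to `[0, 255]` before
#' the next; the result is rounded once at the end. Contrast pivots on the
#' per-image mean rather than mid-gray so a factor near 1 is a near-identity
#' at any exposure.
#'
#' @inheritParams crop_borders
#' @param brightness,contrast,saturation multiplicative factors (> 0).
#' @param gamma gamma exponent (> 0); 1 is the identity.
#' @return the adjusted [rgb_image()].
#' @export
photometric_stage <- function(image, brightness = 1, contrast = 1,
                              saturation = 1, gamma = 1) {
  image <- as_rgb_image(image)
  stopifnot(brightness > 0, contrast > 0, saturation > 0, gamma > 0)
  arr <- unclass(image) * 1.0
  arr <- clip8(arr * brightness)
  m <- mean(arr)
  arr <- clip8(m + contrast * (arr - m))
  L <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  for (ch in 1:3) arr[, , ch] <- L + saturation * (arr[, , ch] - L)
  arr <- clip8(arr)
  arr <- clip8(255 * (arr / 255)^(1 / gamma))
  rgb_image(round_half_up(arr))
}

#' Light Gaussian blur
#'
#' Per-channel separable convolution with a normalized Gaussian kernel of the
#' given odd size (`sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8`), symmetric border
#' reflection. Disrupts low-level, pixel-exact feature memorization.
#'
#' @inheritParams crop_borders
#' @param kernel odd kernel size in pixels; 1 is the identity.
#' @return the blurred [rgb_image()].
#' @export
blur_stage <- function(image, kernel = 3) {
  image <- as_rgb_image(image)
  if (kernel %% 2 != 1 || kernel < 1) stop("`kernel` must be odd and >= 1", call. = FALSE)
  if (kernel == 1) return(image)
  k <- gaussian_kernel_size(kernel)
  rgb_image(clip8(round_half_up(conv_sep_rgb(unclass(image) * 1.0, k))))
}

#' Additive Gaussian pixel noise
#'
#' Adds independent centred Gaussian noise per pixel and channel, clipped to
#' `[0, 255]`. Seeded, so a given `(image, sd, seed)` always produces the
#' same output.
#'
#' @inheritParams crop_borders
#' @param sd noise standard deviation in intensity units.
#' @param seed integer seed.
#' @return the noised [rgb_image()].
#' @export
noise_stage <- function(image, sd, seed) {
  image <- as_rgb_image(image)
  stopifnot(sd >= 0)
  if (sd == 0) return(image)
  arr <- unclass(image) * 1.0
  noise <- with_seed(seed, array(stats::rnorm(length(arr), 0, sd), dim = dim(arr)))
  rgb_image(clip8(round_half_up(arr + noise)))
}

#' Smoothed random perturbation
#'
#' Draws a white-noise field over the image plane, smooths it with a Gaussian
#' filter of sd `smooth_sd` pixels, rescales the field so its maximum
#' absolute value equals `amplitude`, and adds it to all three channels
#' (clipped). The resulting low-frequency warp of intensities is invisible to
#' a human reader but decorrelates the image from any memorized original.
#'
#' @inheritParams crop_borders
#' @param amplitude maximum absolute perturbation, intensity units.
#' @param smooth_sd Gaussian smoothing sd in pixels.
#' @param seed integer seed.
#' @return the perturbed [rgb_image()].
#' @export
smoothed_perturbation_stage <- function(image, amplitude, smooth_sd, seed) {
  image <- as_rgb_image(image)
  stopifnot(amplitude >= 0, smooth_sd >= 0)
  if (amplitude == 0) return(image)
  field <- perturbation_field(dim(image)[1], dim(image)[2], amplitude, smooth_sd, seed)
  arr <- unclass(image) * 1.0
  for (ch in 1:3) arr[, , ch] <- arr[, , ch] + field
  rgb_image(clip8(round_half_up(arr)))
}

# the (deterministic, seeded) additive field used by the perturbation stage
perturbation_field <- function(h, w, amplitude, smooth_sd, seed) {
  field <- with_seed(seed, matrix(stats::rnorm(h * w), h, w))
  if (smooth_sd > 0) field <- conv_sep(field, gaussian_kernel_sigma(smooth_sd))
  mx <- max(abs(field))
  if (mx > 0) field <- field * (amplitude / mx)
  field
}

#' Sample the random parameters of one pipeline run
#'
#' Draws the scale, rotation, brightness, contrast, saturation and gamma
#' values uniformly from their configured ranges, plus the sub-seeds of the
#' two stochastic stages, all from a single integer seed.
#'
#' @param config a [transform_config()].
#' @param seed integer seed.
#' @return a named list with elements `scale`, `angle_deg`, `brightness`,
#'   `contrast`, `saturation`, `gamma`, `noise_seed`, `perturb_seed`.
#' @export
sample_transform_params <- function(config, seed) {
  validate_transform_config(config)
  runif1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  with_seed(seed, {
    p <- list(scale = runif1(config$scale_range),
              angle_deg = runif1(config$rotation_range_deg),
              brightness = runif1(config$brightness_range),
              contrast = runif1(config$contrast_range),
              saturation = runif1(config$saturation_range),
              gamma = runif1(config$gamma_range))
    p$noise_seed <- sample.int(2147483646L, 1)
    p$perturb_seed <- sample.int(2147483646L, 1)
    p
  })
}

#' Apply the full ten-stage transformation to one image
#'
#' Runs, in order: border crop, white padding, rescaling, rotation,
#' brightness/contrast, saturation, gamma, Gaussian blur, Gaussian noise and
#' the smoothed perturbation, with all random parameters drawn from `seed`.
#' Returns both the transformed image and a complete record of the sampled
#' values, from which the output can be reproduced bit-exactly.
#'
#' @inheritParams crop_borders
#' @param config a [transform_config()].
#' @param seed integer seed.
#' @param image_id identifier carried into the record.
#' @return a list with elements `image` (the transformed [rgb_image()]) and
#'   `record` (a one-row data frame: image_id, seed, scale, angle_deg,
#'   brightness, contrast, saturation, gamma, in_h, in_w, out_h, out_w).
#' @export
transform_image <- function(image, config = transform_config(), seed,
                            image_id = "image") {
  image <- as_rgb_image(image)
  validate_transform_config(config)
  p <- sample_transform_params(config, seed)
  in_dim <- dim(image)
  out <- crop_borders(image, config$crop_fraction_per_side)
  out <- add_padding(out, config$pad_fraction, config$pad_color)
  out <- geometric_stage(out, p$scale, p$angle_deg, fill = config$pad_color)
  out <- photometric_stage(out, brightness = p$brightness, contrast = p$contrast,
                           saturation = p$saturation, gamma = p$gamma)
  out <- blur_stage(out, config$blur_kernel)
  out <- noise_stage(out, config$noise_sd, p$noise_seed)
  out <- smoothed_perturbation_stage(out, config$perturb_amplitude,
                                     config$perturb_smooth_sd, p$perturb_seed)
  record <- data.frame(image_id = image_id, seed = seed,
                       scale = p$scale, angle_deg = p$angle_deg,
                       brightness = p$brightness, contrast = p$contrast,
                       saturation = p$saturation, gamma = p$gamma,
                       in_h = in_dim[1], in_w = in_dim[2],
                       out_h = dim(out)[1], out_w = dim(out)[2])
  list(image = out, record = record)
}

#' Transform every image in a directory
#'
#' Applies [transform_image()] to each PNG in `input_dir`, writing the
#' transformed PNGs to `output_dir` and a CSV of transform records alongside
#' them. Per-image seeds are derived from `master_seed` and the file name, so
#' adding images to the directory does not change existing outputs. Originals
#' are never modified. Unreadable files are skipped with a warning and the
#' batch continues.
#'
#' @param input_dir directory of input PNG images.
#' @param output_dir output directory (created if absent).
#' @param config a [transform_config()].
#' @param master_seed integer master seed.
#' @param records_csv path of the records CSV (default
#'   `file.path(output_dir, "transform_records.csv")`).
#' @return (invisibly) the data frame of transform records.
#' @export
transform_batch <- function(input_dir, output_dir, config = transform_config(),
                            master_seed = 1,
                            records_csv = file.path(output_dir, "transform_records.csv")) {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir, call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(input_dir, pattern = "\\.png$", ignore.case = TRUE))
  records <- list()
  for (f in files) {
    res <- tryCatch({
      img <- read_image_png(file.path(input_dir, f))
      id <- sub("\\.png$", "", f, ignore.case = TRUE)
      tr <- transform_image(img, config, seed = derive_seed(master_seed, id),
                            image_id = id)
      write_image_png(tr$image, file.path(output_dir, f))
      tr$record
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", f, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) records[[length(records) + 1]] <- res
  }
  records <- if (length(records)) do.call(rbind, records) else empty_record_df()
  utils::write.csv(records, records_csv, row.names = FALSE)
  invisible(records)
}

empty_record_df <- function() {
  data.frame(image_id = character(), seed = integer(), scale = numeric(),
             angle_deg = numeric(), brightness = numeric(), contrast = numeric(),
             saturation = numeric(), gamma = numeric(), in_h = integer(),
             in_w = integer(), out_h = integer(), out_w = integer())
}
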