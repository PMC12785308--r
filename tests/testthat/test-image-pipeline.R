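test_that("border crop follows the per-side rounding arithmetic", {
  img <- constant_image(400, 400, c(100, 100, 100))
  expect_equal(dim(crop_borders(img, 0.0075))[1:2], c(394, 394))
  # per-axis arithmetic: 0.0075 * 200 = 1.5 rounds half away from zero to 2
  img2 <- constant_image(100, 200, c(0, 0, 0))
  expect_equal(dim(crop_borders(img2, 0.0075))[1:2], c(98, 196))
  expect_identical(crop_borders(img2, 0), img2)
  expect_error(crop_borders(constant_image(64, 64), 0.5), "consume")
})

test_that("padding adds an exact uniform frame", {
  img <- toy_image(394, 394)
  out <- add_padding(img, 0.015, c(255, 255, 255))
  expect_equal(dim(out)[1:2], c(406, 406)) # round(5.91) = 6 per side
  expect_equal(unname(out[1, 1, ]), c(255L, 255L, 255L))
  expect_equal(unname(out[406, 406, ]), c(255L, 255L, 255L))
  expect_identical(unclass(out)[7:400, 7:400, ], unclass(img)[, , ])
  expect_identical(add_padding(img, 0), img)
})

test_that("geometric stage honours identity, scaling arithmetic and rotation geometry", {
  img <- toy_image(64, 64)
  expect_identical(geometric_stage(img, 1, 0), img)
  big <- constant_image(406, 406, c(50, 50, 50))
  expect_equal(dim(geometric_stage(big, 0.5, 0))[1:2], c(203, 203))
  expect_error(geometric_stage(img, 0, 0), "scale")

  # a single bright off-centre pixel moves to its analytically rotated position
  for (angle in c(0.5, 5)) {
    h <- 101; arr <- array(0, dim = c(h, h, 3))
    src <- c(20, 75) # 1-based (y, x)
    arr[src[1], src[2], ] <- 255
    out <- geometric_stage(rgb_image(arr), 1, angle, fill = c(0, 0, 0))
    M <- unclass(out)[, , 1] * 1.0
    expect_gt(sum(M), 0)
    cy <- sum(row(M) * M) / sum(M); cx <- sum(col(M) * M) / sum(M)
    th <- angle * pi / 180
    c0 <- (h + 1) / 2
    dy <- src[1] - c0; dx <- src[2] - c0
    exp_y <- c0 + cos(th) * dy + sin(th) * dx
    exp_x <- c0 - sin(th) * dy + cos(th) * dx
    expect_lt(sqrt((cy - exp_y)^2 + (cx - exp_x)^2), 1)
  }
})

test_that("photometric stage matches closed-form arithmetic and clips", {
  img <- toy_image(16, 16)
  expect_identical(photometric_stage(img, 1, 1, 1, 1), img)
  gray <- constant_image(32, 32, c(128, 128, 128))
  out <- photometric_stage(gray, brightness = 1.04)
  expect_true(all(out == 133)) # round(128 * 1.04 = 133.12)
  extreme <- photometric_stage(toy_image(16, 16), brightness = 3,
                               contrast = 3, saturation = 2, gamma = 0.3)
  expect_true(all(extreme >= 0 & extreme <= 255))
})

test_that("blur preserves constants, admits kernel-1 identity and conserves mass", {
  gray <- constant_image(20, 20, c(77, 150, 3))
  expect_identical(blur_stage(gray, 3), gray)
  img <- toy_image(16, 16)
  expect_identical(blur_stage(img, 1), img)
  expect_error(blur_stage(img, 4), "odd")

  # single bright pixel: direct 2-D convolution oracle on a 5x5 array
  arr <- array(0, dim = c(5, 5, 3)); arr[3, 3, ] <- 255
  out <- blur_stage(rgb_image(arr), 3)
  sigma <- 0.3 * ((3 - 1) / 2 - 1) + 0.8
  g1 <- exp(-(-1:1)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  K <- outer(g1, g1)
  direct <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (u in -1:1) for (v in -1:1) {
      ii <- min(max(ifelse(i + u < 1, 1 - (i + u), ifelse(i + u > 5, 11 - (i + u), i + u)), 1), 5)
      jj <- min(max(ifelse(j + v < 1, 1 - (j + v), ifelse(j + v > 5, 11 - (j + v), j + v)), 1), 5)
      acc <- acc + K[u + 2, v + 2] * arr[ii, jj, 1]
    }
    direct[i, j] <- acc
  }
  expect_lt(max(abs(out[, , 1] - direct)), 0.5 + 1e-9) # rounding only
  expect_lt(out[3, 3, 1], 255)                          # centre decreased
  expect_lt(abs(sum(out[, , 1]) - 255), 25 * 0.5)       # mass within rounding
})

test_that("noise stage is seeded, calibrated and clipped", {
  img <- constant_image(100, 100, c(128, 128, 128))
  expect_identical(noise_stage(img, 0, 1), img)
  n1 <- noise_stage(img, 2, seed = 5)
  n2 <- noise_stage(img, 2, seed = 5)
  expect_identical(n1, n2)
  big <- constant_image(578, 577, c(128, 128, 128)) # ~1e6 values
  noised <- noise_stage(big, 2, seed = 6)
  # rounding to integers inflates the sd by ~sqrt(1/12) in quadrature
  expect_lt(abs(stats::sd(as.numeric(noised) - 128) - 2.0), 0.05)
})

test_that("smoothed perturbation bounds amplitude and is spatially smooth", {
  img <- toy_image(64, 64)
  expect_identical(smoothed_perturbation_stage(img, 0, 8, 1), img)
  out <- smoothed_perturbation_stage(img, 3, 8, seed = 2)
  expect_lte(max(abs(unclass(out) * 1.0 - unclass(img) * 1.0)), 3 + 0.5)
  field <- trichobench:::perturbation_field(128, 128, 3, 8, seed = 2)
  expect_equal(max(abs(field)), 3)
  lag1 <- stats::cor(c(field[, -1]), c(field[, -ncol(field)]))
  expect_gt(lag1, 0.9)
})

test_that("sampled transform parameters always lie inside their configured ranges", {
  cfg <- transform_config()
  for (seed in 1:1000) {
    p <- sample_transform_params(cfg, seed)
    expect_true(p$scale >= cfg$scale_range[1] && p$scale <= cfg$scale_range[2])
    expect_true(p$angle_deg >= cfg$rotation_range_deg[1] &&
                  p$angle_deg <= cfg$rotation_range_deg[2])
    expect_true(p$brightness >= cfg$brightness_range[1] &&
                  p$brightness <= cfg$brightness_range[2])
    expect_true(p$contrast >= cfg$contrast_range[1] &&
                  p$contrast <= cfg$contrast_range[2])
    expect_true(p$saturation >= cfg$saturation_range[1] &&
                  p$saturation <= cfg$saturation_range[2])
    expect_true(p$gamma >= cfg$gamma_range[1] && p$gamma <= cfg$gamma_range[2])
  }
})

test_that("full pipeline is deterministic and follows dimension arithmetic", {
  img <- toy_image(120, 120, seed = 3)
  t1 <- transform_image(img, transform_config(), seed = 31)
  t2 <- transform_image(img, transform_config(), seed = 31)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$record, t2$record)
  # crop 0.0075: 120 -> 118; pad 0.015: -> 122; scale in [0.9, 1.1]
  expect_gte(t1$record$out_h, round(0.90 * 122) - 1)
  expect_lte(t1$record$out_h, round(1.10 * 122) + 1)
  rec <- t1$record
  expect_true(all(c("image_id", "seed", "scale", "angle_deg", "brightness",
                    "contrast", "saturation", "gamma", "in_h", "in_w",
                    "out_h", "out_w") %in% names(rec)))
  # degenerate config: pipeline is the identity
  tid <- transform_image(img, identity_config(), seed = 4)
  expect_identical(unclass(tid$image), unclass(img))
})

test_that("batch transformation writes outputs, records, and never touches inputs", {
  ind <- file.path(tempdir(), "tb_in"); outd <- file.path(tempdir(), "tb_out")
  unlink(c(ind, outd), recursive = TRUE)
  dir.create(ind)
  for (i in 1:3)
    write_image_png(toy_image(72, 72, seed = i), file.path(ind, sprintf("im%d.png", i)))
  sums <- tools::md5sum(list.files(ind, full.names = TRUE))
  rec <- transform_batch(ind, outd, transform_config(), master_seed = 10)
  expect_equal(nrow(rec), 3)
  expect_equal(sort(list.files(outd, pattern = "^im")),
               c("im1.png", "im2.png", "im3.png"))
  expect_identical(tools::md5sum(list.files(ind, full.names = TRUE)), sums)
  # re-run reproduces outputs byte-identically
  outs1 <- tools::md5sum(list.files(outd, full.names = TRUE, pattern = "png$"))
  transform_batch(ind, outd, transform_config(), master_seed = 10)
  expect_identical(tools::md5sum(list.files(outd, full.names = TRUE, pattern = "png$")),
                   outs1)
  # empty directory -> empty record list
  empt <- file.path(tempdir(), "tb_empty"); dir.create(empt, showWarnings = FALSE)
  expect_equal(nrow(transform_batch(empt, outd, master_seed = 1)), 0)
})

test_that("corrupt files are skipped with a warning and the batch continues", {
  ind <- file.path(tempdir(), "tb_bad"); outd <- file.path(tempdir(), "tb_bad_out")
  unlink(c(ind, outd), recursive = TRUE)
  dir.create(ind)
  write_image_png(toy_image(64, 64), file.path(ind, "good.png"))
  writeLines("not a png", file.path(ind, "broken.png"))
  expect_warning(rec <- transform_batch(ind, outd, master_seed = 2), "broken")
  expect_equal(rec$image_id, "good")
})
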