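# Internal raster primitives. All operate on plain numeric arrays/matrices in
# double precision; callers round and clip back to 8-bit at stage boundaries.

# sample matrix M at fractional coordinates (sy, sx), 0-based, bilinear,
# clamped to the image; `valid` marks coordinates inside the source extent
bilinear_sample <- function(M, sy, sx) {
  h <- nrow(M); w <- ncol(M)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  cy0 <- pmin(pmax(y0, 0), h - 1); cy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  cx0 <- pmin(pmax(x0, 0), w - 1); cx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  i00 <- cbind(c(cy0) + 1, c(cx0) + 1)
  i01 <- cbind(c(cy0) + 1, c(cx1) + 1)
  i10 <- cbind(c(cy1) + 1, c(cx0) + 1)
  i11 <- cbind(c(cy1) + 1, c(cx1) + 1)
  v <- (1 - c(fy)) * ((1 - c(fx)) * M[i00] + c(fx) * M[i01]) +
    c(fy) * ((1 - c(fx)) * M[i10] + c(fx) * M[i11])
  matrix(v, nrow(sy), ncol(sy))
}

# bilinear rescale of an h x w x 3 double array to (oh, ow), centre-aligned
resize_bilinear <- function(arr, oh, ow) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  sy <- (seq_len(oh) - 0.5) * h / oh - 0.5
  sx <- (seq_len(ow) - 0.5) * w / ow - 0.5
  SY <- matrix(sy, oh, ow); SX <- matrix(sx, oh, ow, byrow = TRUE)
  out <- array(0, dim = c(oh, ow, 3))
  for (ch in 1:3) out[, , ch] <- bilinear_sample(arr[, , ch], SY, SX)
  out
}

# rotate about the image centre by `angle` degrees (canvas size preserved),
# bilinear interpolation, exposed regions filled with `fill`
rotate_fill <- function(arr, angle, fill) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  th <- angle * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  Y <- matrix(0:(h - 1), h, w) - cy
  X <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  # inverse map: source coordinates for each destination pixel
  SY <- cy + cos(th) * Y - sin(th) * X
  SX <- cx + sin(th) * Y + cos(th) * X
  inside <- SY >= 0 & SY <= h - 1 & SX >= 0 & SX <= w - 1
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    M <- bilinear_sample(arr[, , ch], SY, SX)
    M[!inside] <- fill[ch]
    out[, , ch] <- M
  }
  out
}

# normalized 1-D Gaussian kernel for a given odd size, sigma by the
# sigma = 0.3 * ((k - 1)/2 - 1) + 0.8 convention
gaussian_kernel_size <- function(size) {
  stopifnot(size >= 1, size %% 2 == 1)
  if (size == 1) return(1)
  sigma <- 0.3 * ((size - 1) / 2 - 1) + 0.8
  gaussian_kernel_sigma(sigma, size)
}

gaussian_kernel_sigma <- function(sigma, size = 2 * ceiling(3 * sigma) + 1) {
  if (sigma <= 0) return(1)
  r <- (size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# reflected (symmetric, edge repeated) then clamped index sequence for padding
reflect_index <- function(n, r) {
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), rev(seq_len(n))[seq_len(min(r, n))])
  if (r > n) idx <- c(rep(1L, r - n), idx, rep(n, r - n)) # tiny-image fallback
  idx
}

# separable convolution of a matrix with a 1-D kernel along both axes,
# symmetric border reflection
conv_sep <- function(M, kernel) {
  K <- length(kernel)
  if (K == 1) return(M * kernel)
  r <- (K - 1) / 2
  conv1 <- function(A) { # along rows (dim 1)
    P <- A[reflect_index(nrow(A), r), , drop = FALSE]
    out <- matrix(0, nrow(A), ncol(A))
    for (j in seq_len(K)) out <- out + kernel[j] * P[(j - 1) + seq_len(nrow(A)), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(M))))
}

conv_sep_rgb <- function(arr, kernel) {
  out <- array(0, dim = dim(arr))
  for (ch in 1:3) out[, , ch] <- conv_sep(arr[, , ch], kernel)
  out
}
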