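# Independent brute-force oracles used to check the package's vectorized
# implementations. Deliberately written as plain loops over definitions.

# number of 8-connected components of TRUE pixels in a logical matrix
oracle_count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  comp <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    queue <- list(c(i, j)); lab[i, j] <- comp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- comp
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  comp
}

# two-sided Fisher exact p for a 2x2 table by full enumeration of the
# hypergeometric distribution over tables with the observed margins
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Wilson interval by grid inversion of the score test
oracle_wilson_grid <- function(k, n, level = 0.95, step = 1e-4) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- seq(0, 1, by = step)
  ok <- abs(k / n - p) <= z * sqrt(p * (1 - p) / n)
  range(p[ok])
}

# mean local SSIM by direct per-pixel sliding-window evaluation with a
# Gaussian-weighted 7x7 window and symmetric border reflection
oracle_ssim <- function(X, Y, win = 7, sigma = 1.5) {
  h <- nrow(X); w <- ncol(X)
  r <- (win - 1) / 2
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    i <- ifelse(i > n, 2 * n + 1 - i, i)
    pmin(pmax(i, 1), n)
  }
  total <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- refl(i + (-r):r, h); cj <- refl(j + (-r):r, w)
    x <- X[ri, cj]; y <- Y[ri, cj]
    mx <- sum(W * x); my <- sum(W * y)
    vx <- sum(W * x^2) - mx^2; vy <- sum(W * y^2) - my^2
    cxy <- sum(W * x * y) - mx * my
    total <- total + ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  total / (h * w)
}

# multi-rater agreement by explicit enumeration of rater pairs per item
# (independent route to the r_ik(r_ik - 1) formula)
oracle_ac1 <- function(m) {
  a_i <- c(); f_i <- c()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]; col <- col[!is.na(col)]
    if (length(col) < 2) next
    pairs <- utils::combn(length(col), 2)
    agree <- mean(col[pairs[1, ]] == col[pairs[2, ]])
    a_i <- c(a_i, agree)
    f_i <- c(f_i, mean(col == 1))
  }
  p_a <- mean(a_i); pi_ <- mean(f_i); p_e <- 2 * pi_ * (1 - pi_)
  (p_a - p_e) / (1 - p_e)
}

# identity-configured pipeline (every stage a no-op)
identity_config <- function() {
  transform_config(crop_fraction_per_side = 0, pad_fraction = 0,
                   scale_range = c(1, 1), rotation_range_deg = c(0, 0),
                   brightness_range = c(1, 1), contrast_range = c(1, 1),
                   saturation_range = c(1, 1), gamma_range = c(1, 1),
                   blur_kernel = 1, noise_sd = 0, perturb_amplitude = 0)
}

# small deterministic test image with some structure
toy_image <- function(h = 32, w = 32, seed = 1) {
  vals <- trichobench:::with_seed(seed, sample(0:255, h * w * 3, replace = TRUE))
  rgb_image(array(vals, dim = c(h, w, 3)))
}
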