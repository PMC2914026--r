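# Shared in-code fixtures for the test suite. Everything is generated
# deterministically; no image files are stored.

ramp_image <- function(n = 16, angle = 0, slope = 1) {
  co <- outer(rep(1, n), seq_len(n))
  ro <- outer(seq_len(n), rep(1, n))
  slope * (cos(angle) * co + sin(angle) * ro)
}

step_image <- function(n = 64, lo = 0.2, hi = 0.8, noise = 0, seed = 42) {
  img <- matrix(lo, n, n)
  img[, (n / 2 + 1):n] <- hi
  if (noise > 0) {
    set.seed(seed)
    img <- img + matrix(stats::runif(n * n, -noise, noise), n, n)
  }
  img
}

flat_rgb <- function(value = 0.5, n = 16) {
  array(value, c(n, n, 3))
}

random_rgb <- function(n = 32, seed = 7) {
  set.seed(seed)
  array(stats::runif(n * n * 3), c(n, n, 3))
}

# Brute-force valid convolution with replicate padding, the independent
# oracle for the FFT-backed path.
naive_conv <- function(x, k) {
  pr <- (nrow(k) - 1) %/% 2
  pc <- (ncol(k) - 1) %/% 2
  ri <- c(rep(1, pr), seq_len(nrow(x)), rep(nrow(x), pr))
  ci <- c(rep(1, pc), seq_len(ncol(x)), rep(ncol(x), pc))
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      out[i, j] <- sum(xp[i:(i + 2 * pr), j:(j + 2 * pc)] * k)
    }
  }
  out
}

# Independent min-max normalization used when checking normalized outputs.
minmax01_for_test <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(array(0, dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

gaussian_blur_for_test <- function(x, sigma) {
  half <- ceiling(3 * sigma)
  g <- stats::dnorm(-half:half, sd = sigma)
  k <- outer(g, g); k <- k / sum(k)
  naive_conv(x, k)
}

is_rgb_image_for_test <- function(x) {
  is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3 && all(is.finite(x))
}

gaussian_kernel_for_test <- function(sigma, side) {
  half <- (side - 1) / 2
  g <- stats::dnorm(-half:half, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

luminance_for_test <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# A colorful, textured scene standing in for a natural image: colored
# shapes on a mid-gray background plus fine texture noise.
fixture_scene_for_test <- function(n = 128, texture = 0.05) {
  img <- array(0.5, c(n, n, 3))
  sq <- round(n * 0.15):round(n * 0.45)
  img[sq, sq, 1] <- 0.9; img[sq, sq, 2] <- 0.7; img[sq, sq, 3] <- 0.3
  cc <- round(n * 0.68); rad <- round(n * 0.16)
  disc <- outer((1:n - cc)^2, (1:n - cc)^2, `+`) <= rad^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- c(0.15, 0.25, 0.6)[ch]
    img[, , ch] <- plane
  }
  img <- img + array(stats::rnorm(n * n * 3, 0, texture), c(n, n, 3))
  pmin(pmax(img, 0), 1)
}

gray_to_rgb_for_test <- function(x) {
  out <- array(0, c(dim(x), 3))
  out[, , 1] <- x; out[, , 2] <- x; out[, , 3] <- x
  out
}
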