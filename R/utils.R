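# Internal helpers shared across modules. Images are base-R numeric arrays,
# H x W (grayscale matrix) or H x W x 3 (RGB), working range [0, 1].

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

is_rgb_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

check_image <- function(x, channels = c("any", "gray", "rgb"),
                        arg = deparse(substitute(x))) {
  channels <- match.arg(channels)
  if (!is.numeric(x) || !(is_gray_image(x) || is_rgb_image(x)))
    stop(sprintf("`%s` must be a numeric H x W matrix or H x W x 3 array", arg),
         call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (channels == "gray" && !is_gray_image(x))
    stop(sprintf("`%s` must be single-channel (a matrix)", arg), call. = FALSE)
  if (channels == "rgb" && !is_rgb_image(x))
    stop(sprintf("`%s` must be a 3-channel RGB array", arg), call. = FALSE)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Min-max scaling to [0, 1]; an (effectively) flat input maps to all zeros,
# so uniform images never produce NaNs and FFT roundoff on constants is not
# amplified into spurious structure. 1e-12 is far below any change a single
# 8-bit quantization level (1/255) can induce in a gradient.
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 1e-12) return(array(0, dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Shift a matrix by (dr, dc) with replicate (clamp-to-edge) indexing, so
# out[i, j] = x[clamp(i + dr), clamp(j + dc)].
shift_replicate <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

pad_replicate <- function(x, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(x)), rep(nrow(x), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(x)), rep(ncol(x), pc))
  x[ri, ci, drop = FALSE]
}

# 2-D correlation with an odd-sided kernel under replicate borders. The image
# is padded explicitly so EBImage::filter2 (FFT-based) never sees the border;
# this also lifts filter2's requirement that the image be at least kernel-sized.
conv2_replicate <- function(x, k) {
  pr <- (nrow(k) - 1L) %/% 2L
  pc <- (ncol(k) - 1L) %/% 2L
  xp <- pad_replicate(x, pr, pc)
  y <- EBImage::filter2(xp, k, boundary = "circular")
  y[(pr + 1L):(pr + nrow(x)), (pc + 1L):(pc + ncol(x)), drop = FALSE]
}

# Unit-sum Gaussian kernel; default side spans +/- 3 sigma.
gaussian_kernel <- function(sigma, side = 2L * ceiling(3 * sigma) + 1L) {
  side <- as.integer(side)
  if (side %% 2L == 0L) side <- side + 1L
  half <- (side - 1L) / 2L
  g <- stats::dnorm(-half:half, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

gaussian_blur <- function(x, sigma, side = 2L * ceiling(3 * sigma) + 1L) {
  conv2_replicate(x, gaussian_kernel(sigma, side))
}

each_channel <- function(img, f) {
  if (is_gray_image(img)) return(f(img))
  out <- img
  for (ch in 1:3) out[, , ch] <- f(img[, , ch])
  out
}

# Full-range YCbCr (BT.601 weights) on [0, 1] images; the single luminance
# definition used by the enhancement algorithms.
rgb_to_ycbcr <- function(img) {
  check_image(img, "rgb")
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- (b - y) * 0.564 + 0.5
  cr <- (r - y) * 0.713 + 0.5
  list(y = y, cb = cb, cr = cr)
}

ycbcr_to_rgb <- function(y, cb, cr) {
  r <- y + 1.403 * (cr - 0.5)
  g <- y - 0.344 * (cb - 0.5) - 0.714 * (cr - 0.5)
  b <- y + 1.773 * (cb - 0.5)
  out <- array(0, c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  clip01(out)
}

luminance <- function(img) {
  if (is_gray_image(img)) return(img)
  rgb_to_ycbcr(img)$y
}

gray_to_rgb <- function(x) {
  out <- array(0, c(dim(x), 3L))
  out[, , 1] <- x; out[, , 2] <- x; out[, , 3] <- x
  out
}

# sRGB <-> CIE Lab (D65), the perceptual opponent space used by the retina
# model: L in [0, 100], a = green(-)/red(+), b = blue(-)/yellow(+).
rgb_to_lab <- function(img) {
  check_image(img, "rgb")
  d <- dim(img)
  m <- matrix(img, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(l = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

lab_to_rgb <- function(l, a, b) {
  d <- dim(l)
  m <- cbind(as.vector(l), as.vector(a), as.vector(b))
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB", clip = TRUE)
  out <- array(0, c(d, 3L))
  out[, , 1] <- matrix(rgb[, 1], d[1], d[2])
  out[, , 2] <- matrix(rgb[, 2], d[1], d[2])
  out[, , 3] <- matrix(rgb[, 3], d[1], d[2])
  clip01(out)
}

# Evaluate f() under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; all in-package randomness funnels through this.
with_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  f()
}
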