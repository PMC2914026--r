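#' Read and write still images
#'
#' `read_image()` loads an 8-bit PNG or JPEG into the float working range
#' `[0, 1]`; grayscale files are promoted to 3 channels by replication and
#' any alpha channel is dropped. `write_image()` quantizes to 0-255 with
#' round-half-up and writes PNG (lossless; a PNG round trip changes no
#' pixel by more than 1/255) or JPEG (lossy).
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @param image For `write_image()`: grayscale matrix or RGB array in
#'   `[0, 1]`.
#' @return `read_image()`: an `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("JPEG support requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, " (PNG or JPEG expected)",
         call. = FALSE))
  if (is.matrix(img)) return(gray_to_rgb(img))
  if (dim(img)[3] >= 3L) return(img[, , 1:3, drop = FALSE] + 0)
  gray_to_rgb(img[, , 1])
}

#' @rdname read_image
#' @export
write_image <- function(path, image) {
  check_image(image)
  # round-half-up quantization to 8 bits; exact k/255 values then survive
  # the PNG writer unchanged
  q <- floor(clip01(image) * 255 + 0.5) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("JPEG support requires the 'jpeg' package", call. = FALSE)
      jpeg::writeJPEG(q, path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read and write frame sequences
#'
#' Videos are handled as directories of lexicographically ordered PNG
#' frames -- the lossless, dependency-light canonical path. `read_video()`
#' loads all frames (which must share a shape); `write_video()` writes a
#' frame list as zero-padded PNGs.
#'
#' @param path Directory of `.png` frames.
#' @param frames List of same-shape images.
#' @param fps Nominal frame rate stored as an attribute (default 25).
#' @return `read_video()`: list of RGB arrays with an `fps` attribute.
#' @export
read_video <- function(path, fps = 25) {
  if (!dir.exists(path))
    stop("`path` must be a directory of PNG frames: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no PNG frames found in ", path, call. = FALSE)
  frames <- lapply(files, read_image)
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("mixed frame shapes in ", path, call. = FALSE)
  attr(frames, "fps") <- fps
  frames
}

#' @rdname read_video
#' @export
write_video <- function(frames, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    write_image(file.path(path, sprintf("frame_%05d.png", i)), frames[[i]])
  }
  invisible(path)
}

#' Synthetic test fixtures
#'
#' Deterministic scene generators standing in for natural test material:
#' \describe{
#'   \item{`low_contrast_shapes`}{Mid-gray background with geometric shapes
#'     at Weber-like contrasts 0.05-0.3 plus fine texture noise.}
#'   \item{`noise_ramp`}{Horizontal linear ramp with additive Gaussian
#'     noise of standard deviation `noise_sd`.}
#'   \item{`moving_square_video`}{Frame list with a bright square
#'     translating 2 px per frame across a plain background.}
#'   \item{`pelli_robson`}{The contrast-sensitivity stimulus descriptors
#'     (delegates to [pelli_robson_set()]).}
#'   \item{`face_scene`}{Plain background with synthetic faces (skin-tone
#'     discs with eyes and mouth) at fixed positions, detectable by
#'     [blob_face_detector()].}
#' }
#' Identical `kind`, `size` and `seed` give bitwise-identical output.
#'
#' @param kind Fixture kind, one of the names above.
#' @param size Image side (square frames), default 256.
#' @param seed RNG seed for the noise components.
#' @param n_frames Frame count for the video fixture.
#' @param noise_sd Noise level for `noise_ramp` / texture level for
#'   `low_contrast_shapes`.
#' @param n_faces Number of faces for `face_scene` (1-4).
#' @param face_radius Face radius in pixels for `face_scene`.
#' @return An RGB array, a list of frames, or a `"pelli_set"` depending on
#'   `kind`.
#' @export
#' @examples
#' img <- make_fixture("low_contrast_shapes", size = 64, seed = 1)
#' dim(img)
make_fixture <- function(kind = c("low_contrast_shapes", "noise_ramp",
                                  "moving_square_video", "pelli_robson",
                                  "face_scene"),
                         size = 256L, seed = 1L, n_frames = 20L,
                         noise_sd = 0.02, n_faces = 3L, face_radius = 12L) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("unknown fixture kind; expected one of: low_contrast_shapes, ",
         "noise_ramp, moving_square_video, pelli_robson, face_scene",
         call. = FALSE))
  n <- as.integer(size)
  switch(kind,
    low_contrast_shapes = with_seed(seed, function() {
      img <- array(0.5, c(n, n, 3L))
      add_rect <- function(r, c, hh, ww, delta) {
        rows <- max(1, r):min(n, r + hh); cols <- max(1, c):min(n, c + ww)
        img[rows, cols, ] <<- img[rows, cols, ] + delta
      }
      add_rect(round(n * 0.1), round(n * 0.1), round(n * 0.25), round(n * 0.3), 0.05)
      add_rect(round(n * 0.55), round(n * 0.15), round(n * 0.3), round(n * 0.2), -0.15)
      cc <- round(n * 0.7); rad <- round(n * 0.15)
      disc <- outer((1:n - round(n * 0.3))^2, (1:n - cc)^2, `+`) <= rad^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[disc] <- plane[disc] + 0.3 * c(1, 0.9, 0.7)[ch]
        img[, , ch] <- plane
      }
      img <- img + array(stats::rnorm(n * n * 3, 0, noise_sd), c(n, n, 3L))
      clip01(img)
    }),
    noise_ramp = with_seed(seed, function() {
      ramp <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n,
                     byrow = TRUE)
      if (noise_sd > 0)
        ramp <- ramp + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
      gray_to_rgb(clip01(ramp))
    }),
    moving_square_video = {
      side <- max(8L, round(n / 8))
      frames <- vector("list", n_frames)
      for (t in seq_len(n_frames)) {
        f <- array(0.3, c(n, n, 3L))
        r0 <- round(n / 2 - side / 2)
        c0 <- min(n - side, 2L * (t - 1L) + round(n * 0.1))
        f[r0:(r0 + side), c0:(c0 + side), ] <- 0.9
        frames[[t]] <- f
      }
      attr(frames, "fps") <- 25
      frames
    },
    pelli_robson = pelli_robson_set(retina_geometry(c(n, n))),
    face_scene = {
      img <- array(0.45, c(n, n, 3L))
      patch <- draw_face_patch(face_radius)
      side <- dim(patch)[1]
      spots <- list(c(0.25, 0.25), c(0.3, 0.7), c(0.7, 0.35), c(0.72, 0.75))
      for (k in seq_len(min(n_faces, 4L))) {
        r0 <- round(n * spots[[k]][1]); c0 <- round(n * spots[[k]][2])
        rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
        if (max(rows) > n || max(cols) > n) next
        img[rows, cols, ] <- patch
      }
      img
    })
}
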