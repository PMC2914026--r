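#' Retinal geometry for an image
#'
#' Maps the physical dimensions of the human retina onto pixel space under
#' the assumption that the input image spans the retinal extent (one pixel
#' per cone). Defaults: retina 42 mm, fovea 1 mm, macula 6 mm.
#'
#' @param image_shape Integer `(H, W)` of the image the geometry refers to.
#' @param retina_mm,fovea_mm,macula_mm Physical diameters in millimetres.
#' @return An object of class `"retina_geometry"`.
#' @export
#' @examples
#' g <- retina_geometry(c(800, 800))
#' fovea_px(g)   # 20
#' macula_px(retina_geometry(c(1008, 800)))  # 144
retina_geometry <- function(image_shape, retina_mm = 42, fovea_mm = 1,
                            macula_mm = 6) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) < 2L || any(image_shape < 1L))
    stop("`image_shape` must give positive (H, W)", call. = FALSE)
  structure(list(image_shape = image_shape[1:2], retina_mm = retina_mm,
                 fovea_mm = fovea_mm, macula_mm = macula_mm),
            class = "retina_geometry")
}

#' @export
print.retina_geometry <- function(x, ...) {
  cat(sprintf("Retina geometry for %d x %d image: fovea %d px, macula %.1f px (retina %g mm, fovea %g mm, macula %g mm)\n",
              x$image_shape[1], x$image_shape[2], fovea_px(x), macula_px(x),
              x$retina_mm, x$fovea_mm, x$macula_mm))
  invisible(x)
}

#' @rdname retina_geometry
#' @param geom A `"retina_geometry"` object.
#' @param side Image side length in pixels the conversion refers to; defaults
#'   to the larger image dimension (the axis assumed to span the retina).
#' @details `fovea_px()` rounds up to the nearest even integer so the foveal
#'   patch can be centered symmetrically; `macula_px()` is the exact (possibly
#'   fractional) pixel diameter of the macula.
#' @export
fovea_px <- function(geom, side = max(geom$image_shape)) {
  v <- side * geom$fovea_mm / geom$retina_mm
  p <- ceiling(v)
  if (p %% 2 == 1) p <- p + 1
  as.integer(p)
}

#' @rdname retina_geometry
#' @export
macula_px <- function(geom, side = max(geom$image_shape)) {
  side * geom$macula_mm / geom$retina_mm
}

#' Space-variant foveated blur
#'
#' Simulates the eccentricity-dependent resolution of the retina. A square
#' foveal patch (side [fovea_px()]) centered on the fixation point passes
#' through 1:1; outside it, concentric one-pixel rings at distance `r` from
#' the foveal boundary are blurred with a Gaussian of standard deviation
#' `sigma(r) = max(log(r), sigma_floor)`, so blur grows monotonically with
#' eccentricity. Ring sigmas are discretized to a 0.25 px grid so only a few
#' dozen full-image blurs are needed regardless of image size.
#'
#' @param image Grayscale matrix or RGB array in the working range.
#' @param fovea_xy Fixation point `(row, col)`, 1-based, inside the image.
#' @param geom A [retina_geometry()] (defaults to the image's own geometry).
#' @param sigma_floor Lower bound on the ring sigma (default 0.3 px).
#' @return Image of identical shape with peripheral blur applied.
#' @export
foveate <- function(image, fovea_xy = NULL, geom = NULL, sigma_floor = 0.3) {
  check_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(geom)) geom <- retina_geometry(c(h, w))
  if (is.null(fovea_xy)) fovea_xy <- c(round(h / 2), round(w / 2))
  if (fovea_xy[1] < 1 || fovea_xy[1] > h || fovea_xy[2] < 1 || fovea_xy[2] > w)
    stop("`fovea_xy` lies outside the image", call. = FALSE)
  half <- fovea_px(geom) / 2
  r0 <- fovea_xy[1]; c0 <- fovea_xy[2]

  # Chebyshev ring index from the foveal square (0 = inside the patch)
  rows <- seq_len(h); cols <- seq_len(w)
  dr <- pmax(r0 - half + 1 - rows, rows - (r0 + half), 0)
  dc <- pmax(c0 - half + 1 - cols, cols - (c0 + half), 0)
  ring <- outer(dr, dc, pmax)

  sig <- matrix(0, h, w)
  outside <- ring >= 1
  sig[outside] <- pmax(log(ring[outside]), sigma_floor)
  sig_q <- round(sig / 0.25) * 0.25
  sig_q[outside] <- pmax(sig_q[outside], sigma_floor)

  out <- image
  for (s in sort(unique(sig_q[outside]))) {
    sel <- sig_q == s & outside
    blurred <- each_channel(image, function(ch) gaussian_blur(ch, s))
    if (is_gray_image(image)) {
      out[sel] <- blurred[sel]
    } else {
      for (chn in 1:3) {
        plane <- out[, , chn]; plane[sel] <- blurred[, , chn][sel]
        out[, , chn] <- plane
      }
    }
  }
  out
}

#' Cone and opponent channel separation
#'
#' Splits an RGB scene into the five cone-level planes used by the retina
#' model -- luminance `L`, red, green, blue, and yellow (`(R + G) / 2`) --
#' plus the perceptual opponent planes: `l_plane` (CIE Lab lightness,
#' 0-100), `gr_plane` (green-negative / red-positive) and `by_plane`
#' (blue-negative / yellow-positive). Achromatic pixels have both opponent
#' planes at zero.
#'
#' @param image RGB array in the working range.
#' @return An object of class `"opponent_channels"` with components `L`,
#'   `R`, `G`, `B`, `Y` (all in `[0, 1]`) and `l_plane`, `gr_plane`,
#'   `by_plane`.
#' @export
#' @examples
#' gray <- array(0.5, c(8, 8, 3))
#' ch <- separate_channels(gray)
#' max(abs(ch$gr_plane))  # 0: gray is achromatic
separate_channels <- function(image) {
  check_image(image, "rgb")
  lab <- rgb_to_lab(image)
  structure(list(
    L = lab$l / 100,
    R = image[, , 1], G = image[, , 2], B = image[, , 3],
    Y = (image[, , 1] + image[, , 2]) / 2,
    l_plane = lab$l, gr_plane = lab$a, by_plane = lab$b),
    class = "opponent_channels")
}

#' Horizontal-cell layer
#'
#' Models the horizontal cells' Gaussian-weighted spatial averaging of the
#' cone outputs: each cone plane is smoothed with a unit-sum Gaussian of
#' standard deviation `sigma_h`, and the opponent planes are recomputed from
#' the smoothed cones.
#'
#' @param ch An `"opponent_channels"` object.
#' @param sigma_h Smoothing standard deviation in pixels (default 1).
#' @return A smoothed `"opponent_channels"` object.
#' @export
horizontal_layer <- function(ch, sigma_h = 1) {
  if (!inherits(ch, "opponent_channels"))
    stop("`ch` must come from separate_channels()", call. = FALSE)
  if (!is.finite(sigma_h) || sigma_h <= 0)
    stop("`sigma_h` must be positive", call. = FALSE)
  sm <- function(x) gaussian_blur(x, sigma_h)
  rgb <- array(0, c(dim(ch$R), 3L))
  rgb[, , 1] <- sm(ch$R); rgb[, , 2] <- sm(ch$G); rgb[, , 3] <- sm(ch$B)
  lab <- rgb_to_lab(clip01(rgb))
  structure(list(
    L = sm(ch$L), R = rgb[, , 1], G = rgb[, , 2], B = rgb[, , 3],
    Y = (rgb[, , 1] + rgb[, , 2]) / 2,
    l_plane = lab$l, gr_plane = lab$a, by_plane = lab$b),
    class = "opponent_channels")
}

#' Parameters of the centre-surround (difference-of-Gaussians) filter
#'
#' @param sigma_c Centre Gaussian standard deviation in pixels (default 1).
#' @param sigma_ratio Surround-to-centre sigma ratio (default 2).
#' @param kernel_ratio Surround-to-centre kernel side ratio (default 5),
#'   reflecting the much larger spatial extent of the surround receptive
#'   field.
#' @return An object of class `"dog_params"`.
#' @export
dog_params <- function(sigma_c = 1, sigma_ratio = 2, kernel_ratio = 5) {
  if (!is.finite(sigma_c) || sigma_c <= 0)
    stop("`sigma_c` must be positive", call. = FALSE)
  structure(list(sigma_c = sigma_c, sigma_ratio = sigma_ratio,
                 kernel_ratio = kernel_ratio),
            class = "dog_params")
}

#' Bipolar centre-surround signal
#'
#' Difference of two unit-sum Gaussian low-pass filters: the centre plane
#' filtered at `sigma_c` minus the surround plane filtered at
#' `sigma_ratio * sigma_c` (surround kernel side `kernel_ratio` times the
#' centre side). Equal constant planes yield an identically zero response.
#'
#' @param center_plane,surround_plane Same-shape single-channel planes.
#' @param params A [dog_params()] object.
#' @return Signed single-channel response map.
#' @export
bipolar_dog <- function(center_plane, surround_plane, params = dog_params()) {
  check_image(center_plane, "gray")
  check_image(surround_plane, "gray")
  if (!identical(dim(center_plane), dim(surround_plane)))
    stop("centre and surround planes must share a shape", call. = FALSE)
  side_c <- 2L * ceiling(3 * params$sigma_c) + 1L
  side_s <- as.integer(params$kernel_ratio * side_c)
  sigma_s <- params$sigma_ratio * params$sigma_c
  conv2_replicate(center_plane, gaussian_kernel(params$sigma_c, side_c)) -
    conv2_replicate(surround_plane, gaussian_kernel(sigma_s, side_s))
}

#' The five opponent centre-surround signals
#'
#' Computes the retina model's centre-surround bundle from (horizontally
#' smoothed) cone planes: achromatic luminance ON (`l_on`), red-centre /
#' green-surround (`rg`), green-centre / red-surround (`gr`), blue-centre /
#' yellow-surround (`by`) and yellow-centre / blue-surround (`yb`, included
#' for processing symmetry). Also returns the combined signed opponent maps
#' used for reconstruction, `rg_map = (rg - gr) / 2` and
#' `by_map = (by - yb) / 2`, which vanish on achromatic input.
#'
#' @param ch An `"opponent_channels"` object (typically after
#'   [horizontal_layer()]).
#' @param params A [dog_params()] object.
#' @return A list with components `l_on`, `rg`, `gr`, `by`, `yb`, `rg_map`,
#'   `by_map`.
#' @export
opponent_signals <- function(ch, params = dog_params()) {
  if (!inherits(ch, "opponent_channels"))
    stop("`ch` must come from separate_channels()", call. = FALSE)
  sig <- list(
    l_on = bipolar_dog(ch$L, ch$L, params),
    rg   = bipolar_dog(ch$R, ch$G, params),
    gr   = bipolar_dog(ch$G, ch$R, params),
    by   = bipolar_dog(ch$B, ch$Y, params),
    yb   = bipolar_dog(ch$Y, ch$B, params))
  sig$rg_map <- (sig$rg - sig$gr) / 2
  sig$by_map <- (sig$by - sig$yb) / 2
  sig
}

#' Matched gradient field for Poisson reconstruction
#'
#' Forward-difference gradient (`gx[i, j] = I[i, j+1] - I[i, j]`, zero on the
#' trailing edge) whose divergence is exactly the Neumann five-point
#' Laplacian inverted by [reconstruct()]; the pair forms an exact
#' analysis/synthesis round trip.
#'
#' @param image Single-channel matrix.
#' @return A `"gradient_field"` object (its `magnitude` is the Euclidean
#'   norm of the forward differences).
#' @export
reconstruction_gradient <- function(image) {
  check_image(image, "gray")
  h <- nrow(image); w <- ncol(image)
  gx <- cbind(image[, -1, drop = FALSE] - image[, -w, drop = FALSE],
              rep(0, h))
  gy <- rbind(image[-1, , drop = FALSE] - image[-h, , drop = FALSE],
              rep(0, w))
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
                 normalized = FALSE),
            class = "gradient_field")
}

#' Gradient-domain image reconstruction (fast Poisson solver)
#'
#' Recovers the image whose gradient is closest, in the least-squares sense,
#' to a prescribed (possibly non-integrable) gradient field, by solving the
#' Poisson equation `Lap I = div G` under Neumann boundary conditions. The
#' Laplacian is inverted spectrally: the divergence is extended by
#' half-sample even symmetry and the periodic problem solved with the FFT
#' (equivalent to a discrete cosine transform), so the solve is exact up to
#' floating point and costs `O(HW log HW)`. The solution is unique up to an
#' additive constant; the output is recentred to `mean_value`.
#'
#' @param grad A `"gradient_field"` (components `gx`, `gy`).
#' @param mean_value Mean assigned to the reconstruction (default 0).
#' @return Single-channel matrix minimizing `||grad(I) - G||^2`.
#' @export
#' @examples
#' img <- matrix(sin(seq(0, 3, length.out = 32)), 32, 32)
#' rec <- reconstruct(reconstruction_gradient(img), mean_value = mean(img))
#' max(abs(rec - img)) < 1e-9
reconstruct <- function(grad, mean_value = 0) {
  if (!all(c("gx", "gy") %in% names(grad)))
    stop("`grad` must contain gx and gy", call. = FALSE)
  gx <- grad$gx; gy <- grad$gy
  if (!identical(dim(gx), dim(gy)))
    stop("gx and gy must share a shape", call. = FALSE)
  if (!all(is.finite(gx)) || !all(is.finite(gy)))
    stop("gradient field contains non-finite values", call. = FALSE)
  h <- nrow(gx); w <- ncol(gx)

  # divergence with backward differences (adjoint of the forward gradient)
  div <- matrix(0, h, w)
  div <- div + cbind(gx[, 1, drop = FALSE],
                     gx[, -1, drop = FALSE] - gx[, -w, drop = FALSE])
  div <- div + rbind(gy[1, , drop = FALSE],
                     gy[-1, , drop = FALSE] - gy[-h, , drop = FALSE])
  poisson_solve_neumann(div) + mean_value
}

# Spectral Neumann Poisson solve of Lap I = rhs: half-sample even extension
# makes the problem periodic, the FFT inverts the five-point Laplacian
# (eigenvalues 2cos(pi k/H) + 2cos(pi k/W) - 4), and the zero mode is pinned
# to zero mean.
poisson_solve_neumann <- function(rhs) {
  h <- nrow(rhs); w <- ncol(rhs)
  ext <- rbind(rhs, rhs[h:1, , drop = FALSE])
  ext <- cbind(ext, ext[, w:1, drop = FALSE])
  lam <- outer(2 * cos(pi * (0:(2 * h - 1)) / h) - 2,
               2 * cos(pi * (0:(2 * w - 1)) / w) - 2, `+`)
  lam[1, 1] <- 1
  fhat <- stats::fft(ext) / lam
  fhat[1, 1] <- 0
  sol <- Re(stats::fft(fhat, inverse = TRUE)) / (4 * h * w)
  out <- sol[1:h, 1:w, drop = FALSE]
  out - mean(out)
}

#' Reconstruct a channel from its centre-surround response
#'
#' Inverts the bipolar difference-of-Gaussians encoding: in the retinal
#' model the centre-surround response approximates the negative Laplacian
#' of the (smoothed) underlying channel, so the channel is recovered by
#' solving `Lap I = -S` with the spectral Neumann solver. This restores the
#' low spatial frequencies the DoG suppresses, up to an overall gain and an
#' additive constant.
#'
#' @param s Signed centre-surround response plane.
#' @param mean_value Mean assigned to the reconstruction (default 0).
#' @return Single-channel reconstruction of the encoded channel.
#' @export
reconstruct_from_dog <- function(s, mean_value = 0) {
  check_image(s, "gray")
  poisson_solve_neumann(-s) + mean_value
}

#' Scotoma specification
#'
#' Parameters of a simulated retinal lesion: where the person fixates, how
#' large the degenerated disc is relative to the macula, and what fraction
#' of photoreceptors inside it are lost.
#'
#' @param fovea_xy Fixation pixel `(row, col)`, 1-based.
#' @param size_s Scotoma diameter in macula-diameter units (`>= 0`).
#' @param degree_d Fraction of photoreceptor loss inside the disc, in
#'   `[0, 1]`.
#' @param seed RNG seed making the speckle pattern reproducible.
#' @return An object of class `"scotoma_spec"`.
#' @export
scotoma_spec <- function(fovea_xy, size_s = 1, degree_d = 1, seed = 1L) {
  if (!is.finite(size_s) || size_s < 0)
    stop("`size_s` must be non-negative", call. = FALSE)
  if (!is.finite(degree_d) || degree_d < 0 || degree_d > 1)
    stop("`degree_d` must lie in [0, 1]", call. = FALSE)
  structure(list(fovea_xy = fovea_xy, size_s = size_s, degree_d = degree_d,
                 seed = as.integer(seed)),
            class = "scotoma_spec")
}

dilate8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_replicate(m, dr, dc)
  }
  out
}

#' Binary scotoma mask
#'
#' Generates the photoreceptor-loss mask: inside a disc of diameter
#' `size_s * macula_px(geom)` centred on the fixation point, a seeded
#' clustered speckle pattern covering exactly `round(degree_d * n)` of the
#' `n` disc pixels is set to 0 (dead); everything else is 1 (responsive).
#' Speckle is drawn by seeding spots from a random permutation, dilating
#' them by one pixel to form lesion-like clusters, then adjusting
#' deterministically to the exact dead count, which makes the dead-pixel
#' count monotone in both `degree_d` and `size_s`. Discs extending beyond
#' the image are clipped.
#'
#' @param shape Image shape `(H, W)`.
#' @param spec A [scotoma_spec()] object.
#' @param geom A [retina_geometry()] object (defaults to `shape`'s own).
#' @return Numeric `H x W` matrix of 0 (dead) / 1 (alive) values.
#' @export
#' @examples
#' g <- retina_geometry(c(128, 128))
#' m <- scotoma_mask(c(128, 128), scotoma_spec(c(64, 64), 1, 0.5, seed = 2), g)
#' mean(m == 0)  # dead fraction over the whole frame
scotoma_mask <- function(shape, spec, geom = NULL) {
  if (!inherits(spec, "scotoma_spec"))
    stop("`spec` must come from scotoma_spec()", call. = FALSE)
  h <- shape[1]; w <- shape[2]
  if (is.null(geom)) geom <- retina_geometry(c(h, w))
  mask <- matrix(1, h, w)
  radius <- spec$size_s * macula_px(geom) / 2
  if (radius <= 0 || spec$degree_d == 0) return(mask)
  dist2 <- outer((seq_len(h) - spec$fovea_xy[1])^2,
                 (seq_len(w) - spec$fovea_xy[2])^2, `+`)
  disc <- dist2 <= radius^2
  n <- sum(disc)
  if (n == 0L) return(mask)
  target <- round(spec$degree_d * n)
  if (target == 0L) return(mask)
  disc_idx <- which(disc)

  dead <- with_seed(spec$seed, function() {
    perm <- sample.int(n)
    n_seeds <- max(1L, round(target / 5))
    seed_px <- disc_idx[perm[seq_len(min(n_seeds, n))]]
    m <- matrix(FALSE, h, w)
    m[seed_px] <- TRUE
    m <- dilate8(m) & disc
    count <- sum(m)
    rank <- integer(n); rank[perm] <- seq_len(n)   # rank of each disc pixel
    if (count > target) {
      # revive the latest-ranked dead pixels first
      dead_local <- which(m[disc_idx])
      drop <- dead_local[order(rank[dead_local], decreasing = TRUE)]
      m[disc_idx[drop[seq_len(count - target)]]] <- FALSE
    } else if (count < target) {
      alive_local <- which(!m[disc_idx])
      add <- alive_local[order(rank[alive_local])]
      m[disc_idx[add[seq_len(target - count)]]] <- TRUE
    }
    m
  })
  mask[dead] <- 0
  mask
}

#' Fill dead photoreceptor regions from surviving neighbours
#'
#' Replaces dead (mask = 0) pixels by the Gaussian-weighted average of
#' nearby alive pixels -- a normalized masked convolution -- iterating with a
#' growing support until every dead pixel has at least one healthy
#' contributor. Alive pixels pass through unchanged.
#'
#' @param image Grayscale matrix or RGB array.
#' @param mask Numeric/logical `H x W` matrix, 0 = dead, 1 = alive.
#' @param sigma_fill Gaussian weighting sigma in pixels (default 3).
#' @param fill `"diffusive"` (default) iterates the masked convolution with
#'   a growing support until every dead pixel is reached, so even large
#'   solid lesions are inpainted smoothly from their rim. `"masked"`
#'   performs a single pass: dead pixels beyond the kernel's reach of any
#'   healthy pixel stay dark (photoreceptor loss), so a large full-loss
#'   scotoma remains visible as a soft-rimmed dark lesion -- the behaviour
#'   of a retina that has lost the region, and the mode the simulation
#'   pipeline uses.
#' @return Image of identical shape with dead regions filled (or darkened).
#' @export
apply_degeneration <- function(image, mask, sigma_fill = 3,
                               fill = c("diffusive", "masked")) {
  check_image(image)
  fill <- match.arg(fill)
  m0 <- (mask != 0) * 1
  if (!identical(dim(m0), dim(image)[1:2]))
    stop("`mask` shape must match the image", call. = FALSE)
  if (all(m0 == 0))
    stop("mask is entirely dead; nothing to fill from", call. = FALSE)
  if (all(m0 == 1)) return(image)
  fill_plane <- function(plane) {
    cur_mask <- m0
    filled <- plane * m0
    sig <- sigma_fill
    repeat {
      k <- gaussian_kernel(sig)
      num <- conv2_replicate(filled, k)
      den <- conv2_replicate(cur_mask, k)
      newly <- cur_mask == 0 & den > 1e-10
      if (any(newly)) {
        filled[newly] <- num[newly] / den[newly]
        cur_mask[newly] <- 1
      }
      if (fill == "masked") break       # unreached pixels stay at 0 (dark)
      if (!any(cur_mask == 0)) break
      if (!any(newly)) sig <- sig * 2   # widen support until alive pixels reached
    }
    plane * m0 + filled * (1 - m0)
  }
  each_channel(image, fill_plane)
}

#' Degenerate retina simulation pipeline
#'
#' Full forward model of the (possibly degenerate) retina: foveation,
#' optional scotoma generation and photoreceptor-loss ablation, cone and
#' opponent separation, horizontal-layer smoothing, the five centre-surround
#' signals, and gradient-domain Poisson reconstruction of the three
#' information channels sent to the cortex (luminance, red/green,
#' blue/yellow), which are then recombined through the inverse opponent
#' transform. Each reconstructed channel is recentred to the corresponding
#' channel mean of the retinal input (the opponent maps carry no DC) and the
#' result is clipped to the working range.
#'
#' @param image RGB array in the working range.
#' @param fovea_xy Fixation pixel `(row, col)`; defaults to the centre.
#' @param spec Optional [scotoma_spec()]; `NULL` simulates a healthy retina.
#' @param sigma_h Horizontal-layer smoothing sigma (default 1 px).
#' @param dog A [dog_params()] object.
#' @param geom A [retina_geometry()] (defaults to the image's own).
#' @param opponent_gain Scale mapping the unit-range opponent difference
#'   maps onto the +/-100 Lab chroma axes at output (default 100).
#' @param reconstruction How the centre-surround responses are decoded:
#'   `"laplacian"` (default) solves `Lap I = -S`, treating the DoG response
#'   as the curvature of the encoded channel, which restores low-frequency
#'   scene structure; `"gradient"` differentiates the response with the
#'   matched stencil and Poisson-inverts, returning the band-passed response
#'   itself (an edge-map-like representation).
#' @return RGB array: the scene as represented after retinal processing.
#' @export
#' @examples
#' img <- array(0.5, c(64, 64, 3))
#' out <- retina_pipeline(img)   # constant scenes survive almost unchanged
#' max(abs(out - img)) < 1 / 255
retina_pipeline <- function(image, fovea_xy = NULL, spec = NULL, sigma_h = 1,
                            dog = dog_params(), geom = NULL,
                            opponent_gain = 100,
                            reconstruction = c("laplacian", "gradient")) {
  reconstruction <- match.arg(reconstruction)
  check_image(image, "rgb")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(geom)) geom <- retina_geometry(c(h, w))
  if (is.null(fovea_xy)) fovea_xy <- c(round(h / 2), round(w / 2))

  retinal <- foveate(image, fovea_xy, geom)
  if (!is.null(spec)) {
    mask <- scotoma_mask(c(h, w), spec, geom)
    retinal <- apply_degeneration(retinal, mask, fill = "masked")
  }

  ch <- separate_channels(retinal)
  chs <- horizontal_layer(ch, sigma_h)
  sig <- opponent_signals(chs, dog)

  # The chromatic maps are low-pass colour-difference planes, for which the
  # Poisson round trip (differentiate with the matched stencil, invert) is
  # the exact decode. The luminance ON signal is a genuine centre-surround
  # band-pass; "laplacian" decoding inverts it as a curvature map and
  # divides by the DoG's low-frequency gain (sigma_ratio^2 - 1) * sigma_c^2 / 2
  # so smooth scene structure comes back at roughly unit gain.
  rec_exact <- function(plane) reconstruct(reconstruction_gradient(plane))
  l_rec <- if (reconstruction == "laplacian") {
    dc_gain <- (dog$sigma_ratio^2 - 1) * dog$sigma_c^2 / 2
    reconstruct_from_dog(sig$l_on) / dc_gain
  } else {
    rec_exact(sig$l_on)
  }
  rg_rec <- rec_exact(sig$rg_map)
  by_rec <- rec_exact(sig$by_map)

  lab_in <- rgb_to_lab(retinal)
  l_out <- 100 * l_rec + mean(lab_in$l)
  a_out <- opponent_gain * rg_rec + mean(lab_in$a)
  b_out <- opponent_gain * by_rec + mean(lab_in$b)
  lab_to_rgb(pmin(pmax(l_out, 0), 100), a_out, b_out)
}
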