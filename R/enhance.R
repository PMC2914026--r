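#' Parameters for the TRON enhancement
#'
#' TRON (Tinted Reduced Outlined Nature) multiplies the scene by a floored,
#' normalized multi-scale gradient map, suppressing homogeneous regions while
#' keeping tinted color at object boundaries.
#'
#' @param k_threshold Floor `K` in `[0, 1]` applied to the normalized
#'   gradient map; `K = 1` leaves the image untouched, `K = 0` blacks out
#'   homogeneous regions entirely. Default 0.1.
#' @param diffusion [diffusion_params()] for the simplification step.
#' @param pyramid_levels Pyramid depth for the multi-scale gradient.
#' @param gradient_scale How the gradient map is normalized to `[0, 1]`:
#'   `"fixed"` (default) expresses it as a fraction of the image dynamic
#'   range, so a boundary of Weber contrast `c` scores about `c` and faint
#'   boundaries fall below the `K` floor; `"minmax"` rescales by the
#'   per-image maximum, which always drives the strongest boundary to 1
#'   regardless of its contrast.
#' @return An object of class `"tron_params"`.
#' @export
tron_params <- function(k_threshold = 0.1, diffusion = diffusion_params(),
                        pyramid_levels = 3L,
                        gradient_scale = c("fixed", "minmax")) {
  gradient_scale <- match.arg(gradient_scale)
  if (!is.finite(k_threshold) || k_threshold < 0 || k_threshold > 1)
    stop("`k_threshold` must lie in [0, 1]", call. = FALSE)
  if (!inherits(diffusion, "diffusion_params"))
    stop("`diffusion` must come from diffusion_params()", call. = FALSE)
  pyramid_levels <- as.integer(pyramid_levels)
  if (is.na(pyramid_levels) || pyramid_levels < 1L)
    stop("`pyramid_levels` must be a positive integer", call. = FALSE)
  structure(list(k_threshold = k_threshold, diffusion = diffusion,
                 pyramid_levels = pyramid_levels,
                 gradient_scale = gradient_scale),
            class = "tron_params")
}

#' Parameters for image cartoonization
#'
#' @param n_bins Number of luminance quantization bins `N` (default 8).
#' @param tau_min,tau_max Lower/upper clamp thresholds on the normalized
#'   gradient map (defaults 0.1 and 0.4): below `tau_min` the gradient is
#'   zeroed, above `tau_max` it saturates to 1.
#' @param phi_lo,phi_hi Endpoints of the bin-transition sharpness range
#'   (defaults 3 and 25): the clamped gradient is mapped linearly onto
#'   `[phi_lo, phi_hi]`, so bin boundaries are hard only where the gradient
#'   is high.
#' @param diffusion [diffusion_params()] for the luminance simplification.
#' @param gradient_scale Normalization of the gradient map the thresholds
#'   apply to: `"fixed"` (fraction of dynamic range, default) or
#'   `"minmax"`; see [tron_params()].
#' @return An object of class `"cartoon_params"`.
#' @export
cartoon_params <- function(n_bins = 8L, tau_min = 0.1, tau_max = 0.4,
                           phi_lo = 3, phi_hi = 25,
                           diffusion = diffusion_params(),
                           gradient_scale = c("fixed", "minmax")) {
  gradient_scale <- match.arg(gradient_scale)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop("`n_bins` must be a positive integer", call. = FALSE)
  if (!(tau_min >= 0 && tau_min < tau_max && tau_max <= 1))
    stop("need 0 <= tau_min < tau_max <= 1", call. = FALSE)
  if (phi_lo > phi_hi)
    stop("`phi_lo` must not exceed `phi_hi`", call. = FALSE)
  if (!inherits(diffusion, "diffusion_params"))
    stop("`diffusion` must come from diffusion_params()", call. = FALSE)
  structure(list(n_bins = n_bins, tau_min = tau_min, tau_max = tau_max,
                 phi_lo = phi_lo, phi_hi = phi_hi, diffusion = diffusion,
                 gradient_scale = gradient_scale),
            class = "cartoon_params")
}

#' Parameters for edge overlaying
#'
#' @param base_mode Image the recolored edges are composited onto:
#'   `"original"`, `"gaussian_smoothed"` (the 20 x 20 Gaussian comparison
#'   mode), `"anisotropic_smoothed"`, or `"cartoon"`.
#' @param edge_color RGB triple in `[0, 1]`, or `NULL` to pick a default
#'   (black on the cartoon base, saturated green otherwise).
#' @param edge_opacity Alpha of the edge compositing, in `(0, 1]`.
#' @return An object of class `"overlay_params"`.
#' @export
overlay_params <- function(base_mode = c("original", "gaussian_smoothed",
                                         "anisotropic_smoothed", "cartoon"),
                           edge_color = NULL, edge_opacity = 1) {
  base_mode <- tryCatch(match.arg(base_mode), error = function(e)
    stop("`base_mode` must be one of: original, gaussian_smoothed, ",
         "anisotropic_smoothed, cartoon", call. = FALSE))
  if (is.null(edge_color))
    edge_color <- if (base_mode == "cartoon") c(0, 0, 0) else c(0, 1, 0)
  if (length(edge_color) != 3L || any(edge_color < 0 | edge_color > 1))
    stop("`edge_color` must be an RGB triple in [0, 1]", call. = FALSE)
  if (!is.finite(edge_opacity) || edge_opacity <= 0 || edge_opacity > 1)
    stop("`edge_opacity` must lie in (0, 1]", call. = FALSE)
  structure(list(base_mode = base_mode, edge_color = edge_color,
                 edge_opacity = edge_opacity),
            class = "overlay_params")
}

# Shared preprocessing: diffuse the YCbCr luminance, return the smoothed
# luminance, the chroma planes, and the normalized multi-scale gradient map.
simplified_gradient <- function(image, diffusion, pyramid_levels,
                                gradient_scale = "fixed") {
  ycc <- rgb_to_ycbcr(image)
  yd <- anisotropic_diffuse(ycc$y, diffusion)
  g <- pyramid_gradient(yd, pyramid_levels,
                        normalize = gradient_scale)$magnitude
  list(y = yd, cb = ycc$cb, cr = ycc$cr, g = g)
}

#' TRON scene enhancement
#'
#' Computes a normalized multi-scale gradient map on the anisotropically
#' simplified luminance, floors it at `K`, and multiplies every color channel
#' by the resulting weight `W = max(G, K)`. Edges keep their tinted color at
#' full strength; homogeneous regions are dimmed to a fraction `K` of their
#' original intensity. The output never exceeds the input.
#'
#' @param image RGB array in the `[0, 1]` working range.
#' @param params A [tron_params()] object.
#' @return Enhanced RGB array of the same shape.
#' @export
#' @examples
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' out <- tron(img, tron_params(k_threshold = 0.1))
#' all(out <= img + 1e-12)
tron <- function(image, params = tron_params()) {
  check_image(image, "rgb")
  if (!inherits(params, "tron_params"))
    stop("`params` must come from tron_params()", call. = FALSE)
  sg <- simplified_gradient(image, params$diffusion, params$pyramid_levels,
                            params$gradient_scale)
  w <- pmax(sg$g, params$k_threshold)
  each_channel(image, function(ch) ch * w)
}

#' Soft luminance quantization
#'
#' Quantizes a luminance plane on the 0-100 scale into `N` bins with a
#' gradient-controlled soft transition: with bin width `dq = 100/N` and
#' nearest bin center `q`, the output is
#' `Q = q + (dq/2) * tanh(phi * (y - q) / dq)`, where the sharpness `phi`
#' is the clamped normalized gradient mapped linearly from
#' `[tau_min, tau_max]` onto `[phi_lo, phi_hi]`. Bin boundaries are hard
#' where the gradient is high and spread out in smooth regions. A pixel
#' exactly at a bin center is a fixed point for any `phi`.
#'
#' @param y Single-channel luminance in `[0, 100]`.
#' @param g_norm Normalized gradient map in `[0, 1]`, same shape as `y`.
#' @param params A [cartoon_params()] object.
#' @return Quantized luminance in `[0, 100]`, within `dq/2` of a bin center
#'   everywhere and monotone non-decreasing in `y`.
#' @export
soft_quantize_luminance <- function(y, g_norm, params = cartoon_params()) {
  check_image(y, "gray")
  check_image(g_norm, "gray")
  if (!identical(dim(y), dim(g_norm)))
    stop("`y` and `g_norm` shapes mismatch", call. = FALSE)
  if (!inherits(params, "cartoon_params"))
    stop("`params` must come from cartoon_params()", call. = FALSE)
  n <- params$n_bins
  dq <- 100 / n
  idx <- pmin(pmax(floor(y / dq), 0), n - 1)
  q <- (idx + 0.5) * dq
  gc <- pmin(pmax(g_norm, params$tau_min), params$tau_max)
  span <- params$tau_max - params$tau_min
  t <- if (span > 0) (gc - params$tau_min) / span else 1
  phi <- params$phi_lo + (params$phi_hi - params$phi_lo) * t
  q + (dq / 2) * tanh(phi * (y - q) / dq)
}

#' Image cartoonization
#'
#' Produces a flat-shaded, high-contrast stylization: the YCbCr luminance is
#' simplified by anisotropic diffusion, its normalized gradient map is
#' clamped (`< tau_min` to 0, `> tau_max` to 1), the luminance is
#' soft-quantized into bins, the image is converted back to RGB, and all
#' channels are darkened by the negative of the clamped gradient map
#' (multiplication by `1 - g`), drawing dark contours along strong edges.
#'
#' @param image RGB array in the working range.
#' @param params A [cartoon_params()] object.
#' @return Cartoonized RGB array of the same shape.
#' @export
#' @examples
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' cart <- cartoonize(img, cartoon_params(n_bins = 4))
cartoonize <- function(image, params = cartoon_params()) {
  check_image(image, "rgb")
  if (!inherits(params, "cartoon_params"))
    stop("`params` must come from cartoon_params()", call. = FALSE)
  ycc <- rgb_to_ycbcr(image)
  yd <- anisotropic_diffuse(ycc$y, params$diffusion)
  gm <- gradient_field(directional_derivatives(yd))$magnitude
  g <- if (params$gradient_scale == "minmax") minmax01(gm)
       else fixed_gradient_scale(gm)
  gclamp <- g
  gclamp[g < params$tau_min] <- 0
  gclamp[g > params$tau_max] <- 1
  q <- soft_quantize_luminance(yd * 100, g, params) / 100
  out <- ycbcr_to_rgb(q, ycc$cb, ycc$cr)
  clip01(each_channel(out, function(ch) ch * (1 - gclamp)))
}

#' Edge overlaying
#'
#' Extracts significant edges (anisotropic simplification followed by the
#' multi-scale pyramid gradient, binarized at `tau_min`) and alpha-blends
#' them in a highlight color over a chosen base: the original image, a
#' Gaussian-smoothed version (the heavier-handed comparison mode), the
#' anisotropically smoothed image, or the cartoonized image. The edge mask
#' depends only on the gradient settings, not on the base.
#'
#' @param image RGB array in the working range.
#' @param params An [overlay_params()] object.
#' @param cartoon_params A [cartoon_params()] object (supplies `tau_min` for
#'   the edge binarization and the cartoon base).
#' @param tron_params A [tron_params()] object (supplies the diffusion and
#'   pyramid settings of the edge extraction).
#' @return RGB array with recolored edges composited onto the base.
#' @export
edge_overlay <- function(image, params = overlay_params(),
                         cartoon_params = retinasim::cartoon_params(),
                         tron_params = retinasim::tron_params()) {
  check_image(image, "rgb")
  if (!inherits(params, "overlay_params"))
    stop("`params` must come from overlay_params()", call. = FALSE)
  sg <- simplified_gradient(image, tron_params$diffusion,
                            tron_params$pyramid_levels,
                            tron_params$gradient_scale)
  mask <- sg$g >= cartoon_params$tau_min & sg$g > 0
  base <- switch(params$base_mode,
    original = image,
    gaussian_smoothed = each_channel(image, function(ch)
      gaussian_blur(ch, sigma = 10 / 3, side = 21L)),
    anisotropic_smoothed = ycbcr_to_rgb(sg$y, sg$cb, sg$cr),
    cartoon = cartoonize(image, cartoon_params))
  a <- params$edge_opacity
  out <- base
  for (ch in 1:3) {
    plane <- base[, , ch]
    plane[mask] <- (1 - a) * plane[mask] + a * params$edge_color[ch]
    out[, , ch] <- plane
  }
  clip01(out)
}
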