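#' Percentage of extracted edges
#'
#' The perception-efficacy metric used to score processed scenes: the
#' four-direction gradient magnitude of the (luminance of the) image is
#' min-max scaled to 0-255, summed, and expressed as a percentage of the
#' maximal-gradient image: `E = 100 * sum(G_scaled) / (255 * M * N)`.
#' Constant images score 0; the metric is invariant to global intensity
#' offsets and (up to border effects) to 90-degree rotation.
#'
#' @param image Grayscale matrix or RGB array (RGB is converted to
#'   luminance first).
#' @return An object of class `"edge_score"` with fields `percentage`
#'   (in `[0, 100]`) and `image_shape`.
#' @export
#' @examples
#' edge_percentage(matrix(0.5, 32, 32))$percentage  # 0
edge_percentage <- function(image) {
  check_image(image)
  y <- luminance(image)
  g <- gradient_field(directional_derivatives(y))$magnitude
  scaled <- minmax01(g) * 255
  structure(list(percentage = 100 * sum(scaled) / (255 * length(scaled)),
                 image_shape = dim(y)),
            class = "edge_score")
}

#' @export
print.edge_score <- function(x, ...) {
  cat(sprintf("Extracted edges: %.3f%% of a %d x %d image\n",
              x$percentage, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Pelli-Robson style contrast stimuli
#'
#' Builds the descriptor grid of the contrast-sensitivity experiment: a
#' white background with a gray square box whose Weber contrast is
#' `10^(-log_cs)` (so box luminance is `background * (1 - 10^(-log_cs))`),
#' swept over a ladder of `log_cs` values in 0.15 log-unit steps (the
#' chart's triplet increment) and over horizontal eccentricities of the box
#' centre from the image centre. Default design: 16 contrast levels times
#' 14 eccentricities in 30 px steps, on an 800 x 800 frame with box side
#' 44% of the macula diameter. Stimuli whose box would leave the frame are
#' flagged rather than silently clipped.
#'
#' Descriptors are lightweight; call [render_stimulus()] to materialize the
#' pixels of any one stimulus.
#'
#' @param geom A [retina_geometry()] giving the frame size and macula scale.
#' @param n_levels Number of contrast levels (default 16).
#' @param contrast_step Ladder increment in log units (default 0.15).
#' @param ecc_step_px Eccentricity step in pixels (default 30).
#' @param n_ecc Number of eccentricities, starting at 0 (default 14).
#' @param background Background luminance (default 1, white).
#' @return A data frame of class `"pelli_set"` with columns `log_cs`,
#'   `eccentricity_px`, `box_side_px`, `box_luminance`, `background`,
#'   `flagged`.
#' @export
#' @examples
#' set <- pelli_robson_set(retina_geometry(c(800, 800)))
#' nrow(set)  # 16 * 14 = 224
pelli_robson_set <- function(geom, n_levels = 16L, contrast_step = 0.15,
                             ecc_step_px = 30L, n_ecc = 14L,
                             background = 1) {
  if (n_levels < 1L || n_ecc < 1L || ecc_step_px < 0 || contrast_step <= 0)
    stop("sweep parameters must be positive", call. = FALSE)
  h <- geom$image_shape[1]; w <- geom$image_shape[2]
  box_side <- round(0.44 * macula_px(geom))
  log_cs <- contrast_step * (seq_len(n_levels) - 1L)
  ecc <- ecc_step_px * (seq_len(n_ecc) - 1L)
  grid <- expand.grid(log_cs = log_cs, eccentricity_px = ecc,
                      KEEP.OUT.ATTRS = FALSE)
  grid$box_side_px <- box_side
  grid$box_luminance <- background * (1 - 10^(-grid$log_cs))
  grid$background <- background
  half <- floor(box_side / 2)
  c0 <- round(w / 2)
  grid$flagged <- c0 + grid$eccentricity_px + half > w |
    c0 + grid$eccentricity_px - half < 1
  attr(grid, "image_shape") <- c(h, w)
  class(grid) <- c("pelli_set", class(grid))
  grid
}

#' @rdname pelli_robson_set
#' @param set A `"pelli_set"` data frame.
#' @param i Row index of the stimulus to render.
#' @param noise_sd Standard deviation of the additive sensor noise applied
#'   before 8-bit quantization (default half a gray level, `0.5/255`).
#'   Rendered stimuli emulate an 8-bit imaging chain, so a box whose Weber
#'   contrast falls below the quantization/noise floor is genuinely
#'   invisible, as it would be to a camera. Set to 0 (with
#'   `quantize = FALSE`) for exact analytic stimuli.
#' @param quantize Quantize the rendered stimulus to 8 bits (default TRUE).
#' @param seed Seed of the per-stimulus noise; defaults to a value derived
#'   from the row index so every stimulus is deterministic.
#' @return `render_stimulus()`: an RGB array with the box drawn (clipped to
#'   the frame if it overruns).
#' @export
render_stimulus <- function(set, i, noise_sd = 0.5 / 255, quantize = TRUE,
                            seed = NULL) {
  shp <- attr(set, "image_shape")
  row <- set[i, ]
  if (nrow(row) != 1L) stop("`i` must select one stimulus", call. = FALSE)
  h <- shp[1]; w <- shp[2]
  img <- matrix(row$background, h, w)
  half <- floor(row$box_side_px / 2)
  r0 <- round(h / 2); c0 <- round(w / 2) + row$eccentricity_px
  rows <- max(1, r0 - half):min(h, r0 + half)
  cols <- max(1, c0 - half):min(w, c0 + half)
  img[rows, cols] <- row$box_luminance
  if (noise_sd > 0) {
    if (is.null(seed)) seed <- 190000L + as.integer(i)
    img <- img + with_seed(seed, function()
      matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
  }
  img <- clip01(img)
  if (quantize) img <- floor(img * 255 + 0.5) / 255
  gray_to_rgb(img)
}

#' Standard enhancement algorithms as a named list
#'
#' Convenience bundle used by the evaluation sweeps and the CLI: the three
#' scene enhancements at their default settings, as functions image -> image.
#'
#' @param tron_params,cartoon_params,overlay_params Parameter objects used
#'   by the respective algorithm.
#' @return Named list of functions `tron`, `cartoon`, `edges`.
#' @export
standard_enhancers <- function(tron_params = retinasim::tron_params(),
                               cartoon_params = retinasim::cartoon_params(),
                               overlay_params = retinasim::overlay_params()) {
  list(
    tron = function(img) tron(img, tron_params),
    cartoon = function(img) cartoonize(img, cartoon_params),
    edges = function(img) edge_overlay(img, overlay_params, cartoon_params,
                                       tron_params))
}

#' Contrast-sensitivity experiment through the degenerate retina
#'
#' For every requested Pelli-Robson stimulus and every enhancement
#' algorithm (plus an unprocessed passthrough), the stimulus is enhanced,
#' passed through the retina pipeline with a central macula-sized scotoma,
#' and scored with [edge_percentage()]. The result quantifies how much
#' perceivable edge signal each algorithm preserves at each contrast and
#' eccentricity.
#'
#' @param enhancers Named list of functions image -> image; may be empty
#'   (passthrough only). See [standard_enhancers()].
#' @param geom A [retina_geometry()] for the stimulus frame.
#' @param spec A [scotoma_spec()]; defaults to a full-loss macula-sized
#'   scotoma at the frame centre.
#' @param log_cs_values,ecc_values Optional subsets of the contrast ladder
#'   and eccentricity sweep (defaults: the full design).
#' @param sigma_h,dog Retina model settings passed to [retina_pipeline()].
#' @param ... Further arguments to [pelli_robson_set()].
#' @return Data frame with columns `algorithm`, `log_cs`,
#'   `eccentricity_px`, `edge_pct`.
#' @export
run_pelli_experiment <- function(enhancers = list(), geom, spec = NULL,
                                 log_cs_values = NULL, ecc_values = NULL,
                                 sigma_h = 1, dog = dog_params(), ...) {
  set <- pelli_robson_set(geom, ...)
  if (!is.null(log_cs_values))
    set <- set[sapply(set$log_cs, function(v)
      any(abs(v - log_cs_values) < 1e-9)), ]
  if (!is.null(ecc_values))
    set <- set[set$eccentricity_px %in% ecc_values, ]
  h <- geom$image_shape[1]; w <- geom$image_shape[2]
  if (is.null(spec))
    spec <- scotoma_spec(c(round(h / 2), round(w / 2)), size_s = 1,
                         degree_d = 1, seed = 1L)
  algos <- c(list(passthrough = identity), enhancers)
  out <- list()
  for (i in seq_len(nrow(set))) {
    img <- render_stimulus(set, i)
    for (nm in names(algos)) {
      proc <- algos[[nm]](img)
      sim <- retina_pipeline(proc, fovea_xy = spec$fovea_xy, spec = spec,
                             sigma_h = sigma_h, dog = dog, geom = geom)
      out[[length(out) + 1L]] <- data.frame(
        algorithm = nm, log_cs = set$log_cs[i],
        eccentricity_px = set$eccentricity_px[i],
        edge_pct = edge_percentage(sim)$percentage)
    }
  }
  do.call(rbind, out)
}

#' Face-detection degeneration sweep
#'
#' Runs every image through every enhancement algorithm (plus passthrough)
#' and the retina pipeline at increasing scotoma sizes (default 0 to 4
#' macula diameters in 0.4 steps, 11 levels, full photoreceptor loss), then
#' counts faces with the supplied detector. The detector is a pluggable
#' interface: any function image -> data.frame of boxes (one row per
#' detection) works. When no detector is available the sweep degrades to
#' writing the processed frames and a manifest to `out_dir` with a notice,
#' so the images can be scored externally.
#'
#' @param images List of RGB arrays.
#' @param enhancers Named list of functions image -> image.
#' @param geom Optional [retina_geometry()] shared by all images.
#' @param detector Function image -> data.frame of detections, or `NULL`.
#'   See [blob_face_detector()] for the built-in synthetic-face detector.
#' @param levels Degeneration levels in macula-diameter multiples.
#' @param fovea_xy Fixation point shared across the sweep (default centre).
#' @param seed Seed fixed across the sweep so algorithm comparisons differ
#'   only in the enhancement.
#' @param sigma_h,dog Retina model settings.
#' @param out_dir Output directory for the degraded (no-detector) mode.
#' @return Data frame with columns `algorithm`, `degeneration_level`,
#'   `image`, and `faces` (detector mode) or `path` (manifest mode).
#' @export
face_sweep <- function(images, enhancers = list(), geom = NULL,
                       detector = NULL, levels = seq(0, 4, by = 0.4),
                       fovea_xy = NULL, seed = 1L, sigma_h = 1,
                       dog = dog_params(), out_dir = NULL) {
  if (is_rgb_image(images)) images <- list(images)
  algos <- c(list(passthrough = identity), enhancers)
  manifest_mode <- is.null(detector)
  if (manifest_mode) {
    if (is.null(out_dir))
      stop("no `detector` supplied: provide `out_dir` so processed images ",
           "and a manifest can be emitted for external scoring", call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    message("face_sweep: no detector available; writing processed images ",
            "and a manifest to ", out_dir)
  }
  out <- list()
  for (ii in seq_along(images)) {
    img <- images[[ii]]
    h <- dim(img)[1]; w <- dim(img)[2]
    g <- if (is.null(geom)) retina_geometry(c(h, w)) else geom
    fx <- if (is.null(fovea_xy)) c(round(h / 2), round(w / 2)) else fovea_xy
    for (nm in names(algos)) {
      proc <- algos[[nm]](img)
      for (lev in levels) {
        spec <- if (lev > 0)
          scotoma_spec(fx, size_s = lev, degree_d = 1, seed = seed) else NULL
        sim <- retina_pipeline(proc, fovea_xy = fx, spec = spec,
                               sigma_h = sigma_h, dog = dog, geom = g)
        if (manifest_mode) {
          path <- file.path(out_dir, sprintf("img%02d_%s_level%.1f.png",
                                             ii, nm, lev))
          write_image(path, sim)
          out[[length(out) + 1L]] <- data.frame(
            algorithm = nm, degeneration_level = lev, image = ii, path = path)
        } else {
          boxes <- detector(sim)
          out[[length(out) + 1L]] <- data.frame(
            algorithm = nm, degeneration_level = lev, image = ii,
            faces = if (is.null(boxes)) 0L else nrow(boxes))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (manifest_mode) {
    utils::write.csv(res, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  res
}

#' Synthetic-face template detector
#'
#' A deliberately simple detector for the synthetic `face_scene` fixture:
#' normalized cross-correlation against the fixture's face template (a
#' skin-tone disc with dark eyes and mouth) followed by thresholding and
#' greedy non-maximum suppression. It is a stand-in harness detector for
#' exercising [face_sweep()] end to end, not a real face detector.
#'
#' @param radius Face radius in pixels the template is built at (must match
#'   the fixture's).
#' @param threshold Correlation threshold for a detection (default 0.35,
#'   chosen so faces survive the retina model's blur at low degeneration
#'   while flat background never triggers).
#' @return A detector function image -> data.frame with columns `row`,
#'   `col`, `score`.
#' @export
blob_face_detector <- function(radius = 12L, threshold = 0.35) {
  tmpl <- luminance(draw_face_patch(radius))
  tmpl <- tmpl - mean(tmpl)
  tn <- sqrt(sum(tmpl^2))
  side <- nrow(tmpl)
  function(image) {
    y <- luminance(image)
    if (nrow(y) < side || ncol(y) < side) return(NULL)
    ones <- matrix(1, side, side)
    # correlation of the zero-mean template with each local window
    num <- conv2_replicate(y, tmpl[side:1, side:1])
    loc_sum <- conv2_replicate(y, ones)
    loc_sq <- conv2_replicate(y^2, ones)
    loc_var <- pmax(loc_sq - loc_sum^2 / (side^2), 1e-12)
    ncc <- num / (tn * sqrt(loc_var))
    hits <- which(ncc >= threshold, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(data.frame(row = integer(), col = integer(),
                                            score = numeric()))
    hits <- hits[order(ncc[hits], decreasing = TRUE), , drop = FALSE]
    kept <- matrix(NA_real_, 0, 2)
    scores <- numeric()
    for (k in seq_len(nrow(hits))) {
      p <- hits[k, ]
      if (nrow(kept) == 0 ||
          all(sqrt(rowSums((kept - matrix(p, nrow(kept), 2,
                                          byrow = TRUE))^2)) > side / 2)) {
        kept <- rbind(kept, p)
        scores <- c(scores, ncc[p[1], p[2]])
      }
    }
    data.frame(row = kept[, 1], col = kept[, 2], score = scores)
  }
}

# Face patch used by both the face_scene fixture and the template detector.
draw_face_patch <- function(radius = 12L) {
  side <- 2L * radius + 1L
  patch <- array(0.5, c(side, side, 3L))
  cc <- radius + 1L
  d2 <- outer((seq_len(side) - cc)^2, (seq_len(side) - cc)^2, `+`)
  face <- d2 <= radius^2
  skin <- c(0.9, 0.75, 0.6)
  for (ch in 1:3) {
    plane <- patch[, , ch]
    plane[face] <- skin[ch]
    patch[, , ch] <- plane
  }
  eye_r <- max(1L, round(radius / 5))
  for (off in c(-1, 1)) {
    er <- cc - round(radius / 3)
    ec <- cc + off * round(radius / 2.5)
    e2 <- outer((seq_len(side) - er)^2, (seq_len(side) - ec)^2, `+`)
    patch[, , 1][e2 <= eye_r^2] <- 0.1
    patch[, , 2][e2 <= eye_r^2] <- 0.1
    patch[, , 3][e2 <= eye_r^2] <- 0.1
  }
  mr <- cc + round(radius / 2.2)
  mouth_cols <- (cc - round(radius / 3)):(cc + round(radius / 3))
  patch[mr, mouth_cols, 1] <- 0.35
  patch[mr, mouth_cols, 2] <- 0.1
  patch[mr, mouth_cols, 3] <- 0.1
  patch
}

#' Frame-difference motion metric
#'
#' Scores perceivable motion in a frame sequence: for each gap `k` in
#' `gaps`, successive absolute frame differences `|F_t - F_(t-k)|` are
#' computed along the sequence (simulating lower frame rates), each
#' difference image is scored with the extracted-edge procedure of
#' [edge_percentage()], and the final value is the mean over all
#' differences and gaps. Identical frames score 0.
#'
#' @param frames Ordered list of same-shape images.
#' @param gaps Integer frame-index gaps; the default `1:4` measures motion
#'   between 2, 3, 4 and 5 successive frames.
#' @return Single numeric motion percentage.
#' @export
motion_percentage <- function(frames, gaps = 1:4) {
  gaps <- sort(unique(as.integer(gaps)))
  if (any(gaps < 1L)) stop("`gaps` must be positive integers", call. = FALSE)
  if (length(frames) < max(gaps) + 1L)
    stop(sprintf("need at least %d frames for gaps up to %d",
                 max(gaps) + 1L, max(gaps)), call. = FALSE)
  scores <- numeric()
  for (k in gaps) {
    for (t in (k + 1L):length(frames)) {
      d <- abs(frames[[t]] - frames[[t - k]])
      scores <- c(scores, edge_percentage(d)$percentage)
    }
  }
  mean(scores)
}
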