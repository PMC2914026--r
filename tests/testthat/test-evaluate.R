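test_that("edge percentage follows its defining summation", {
  expect_equal(edge_percentage(matrix(0.5, 32, 32))$percentage, 0)
  expect_equal(edge_percentage(flat_rgb(0.3, 16))$percentage, 0)

  # checkerboard oracle: direct per-pixel summation over the explicitly
  # convolved gradient map
  n <- 64
  chk <- (outer(1:n, 1:n, `+`) %% 2) * 0.8 + 0.1
  score <- edge_percentage(chk)$percentage
  d <- directional_derivatives(chk)
  g <- sqrt((d$h + (d$d1 + d$d2) / sqrt(2))^2 +
            (d$v + (d$d1 - d$d2) / sqrt(2))^2)
  g <- (g - min(g)) / (max(g) - min(g)) * 255
  oracle <- 100 * sum(g) / (255 * n * n)
  expect_equal(score, oracle, tolerance = 1e-12)
  expect_gt(score, 0); expect_lt(score, 100)
})

test_that("edge percentage ignores offsets and survives rotation", {
  set.seed(8)
  img <- matrix(runif(48 * 48), 48, 48)
  e0 <- edge_percentage(img)$percentage
  expect_equal(edge_percentage(img + 0.2)$percentage, e0, tolerance = 1e-9)
  e90 <- edge_percentage(t(img[nrow(img):1, ]))$percentage
  expect_lt(abs(e90 - e0) / e0, 0.01)
})

test_that("the Pelli-Robson design matches the published experiment", {
  geom <- retina_geometry(c(800, 800))
  set <- pelli_robson_set(geom)
  expect_equal(nrow(set), 16 * 14)
  expect_equal(length(unique(set$log_cs)), 16)
  expect_equal(length(unique(set$eccentricity_px)), 14)
  expect_equal(max(set$log_cs), 2.25, tolerance = 1e-12)
  expect_equal(unique(set$box_side_px), round(0.44 * macula_px(geom)))

  # Weber contrast is exactly 10^(-log_cs) by construction
  weber <- (set$background - set$box_luminance) / set$background
  expect_equal(weber, 10^(-set$log_cs), tolerance = 1e-12)
  # box luminance falls strictly as the contrast label (and hence the
  # Weber contrast) rises toward log_cs = 0
  one_ecc <- set[set$eccentricity_px == 0, ]
  expect_true(all(diff(one_ecc$box_luminance[order(one_ecc$log_cs,
                                                   decreasing = TRUE)]) < 0))

  # boxes running off the frame are flagged, not clipped silently
  expect_true(any(set$flagged))
  expect_true(all(set$flagged == (set$eccentricity_px == max(set$eccentricity_px))))

  img <- render_stimulus(set, which(set$log_cs == 0)[1])
  expect_equal(min(img), 0)   # log_cs = 0 -> black box
  expect_equal(max(img), 1)
})

test_that("stimulus rendering places the box at the requested eccentricity", {
  geom <- retina_geometry(c(200, 200))
  set <- pelli_robson_set(geom, n_levels = 4, ecc_step_px = 20, n_ecc = 3)
  i <- which(abs(set$log_cs - 0.45) < 1e-9 & set$eccentricity_px == 40)
  img <- render_stimulus(set, i, noise_sd = 0, quantize = FALSE)
  y <- img[, , 1]
  box_cols <- range(which(apply(y < 1, 2, any)))
  expect_equal(mean(box_cols), 100 + 40, tolerance = 1)
  expect_equal(min(y), 1 - 10^(-0.45), tolerance = 1e-12)
})

test_that("an empty enhancer list yields passthrough rows only", {
  geom <- retina_geometry(c(96, 96))
  res <- run_pelli_experiment(list(), geom, n_levels = 2, n_ecc = 1,
                              ecc_step_px = 5)
  expect_equal(unique(res$algorithm), "passthrough")
  expect_equal(nrow(res), 2)
  expect_true(all(res$edge_pct >= 0 & res$edge_pct <= 100))
})

test_that("the pelli experiment is deterministic for a fixed seed", {
  geom <- retina_geometry(c(96, 96))
  enh <- list(tron = function(img) tron(img, tron_params(
    diffusion = diffusion_params(iterations = 3), pyramid_levels = 2)))
  r1 <- run_pelli_experiment(enh, geom, log_cs_values = 0.75, ecc_values = 0)
  r2 <- run_pelli_experiment(enh, geom, log_cs_values = 0.75, ecc_values = 0)
  expect_identical(r1, r2)
})

test_that("TRON beats passthrough on a mid-contrast box outside the scotoma", {
  geom <- retina_geometry(c(160, 160))
  dp <- diffusion_params(iterations = 5)
  enh <- list(tron = function(img) tron(img, tron_params(0.1, dp, 2)))
  # eccentricity 21 px puts the box beyond the macula-sized central scotoma
  res <- run_pelli_experiment(enh, geom, log_cs_values = 0.9,
                              ecc_values = 21, ecc_step_px = 21, n_ecc = 2)
  base <- res$edge_pct[res$algorithm == "passthrough"]
  expect_gt(res$edge_pct[res$algorithm == "tron"], base)
})

test_that("face sweep has 11 default levels and degrades without a detector", {
  expect_equal(length(seq(0, 4, by = 0.4)), 11)

  img <- make_fixture("face_scene", size = 96, n_faces = 1)
  out_dir <- withr::local_tempdir()
  expect_message(
    res <- face_sweep(img, geom = retina_geometry(c(96, 96)),
                      levels = c(0, 2), out_dir = out_dir),
    "no detector")
  expect_true(file.exists(file.path(out_dir, "manifest.csv")))
  expect_equal(nrow(res), 2)
  expect_true(all(file.exists(res$path)))
  expect_error(face_sweep(img, levels = 0), "detector")
})

test_that("detected faces do not increase with degeneration", {
  img <- make_fixture("face_scene", size = 160, n_faces = 3)
  det <- blob_face_detector()
  expect_equal(nrow(det(img)), 3)

  res <- face_sweep(img, detector = det, levels = c(0, 2.4, 4), seed = 1)
  counts <- res$faces[order(res$degeneration_level)]
  expect_equal(res$algorithm, rep("passthrough", 3))
  expect_true(all(diff(counts) <= 1))      # sampling-noise tolerance
  expect_lt(counts[3], counts[1])          # severe loss removes faces
})

test_that("motion percentage is zero for static scenes and matches its oracle", {
  frames <- replicate(6, flat_rgb(0.5, 32), simplify = FALSE)
  expect_equal(motion_percentage(frames), 0)
  expect_error(motion_percentage(frames[1:3], gaps = 4), "at least")

  # alternating checkerboard with gaps = {1}: every difference image is the
  # same, so the score equals the direct summation oracle of |F2 - F1|
  n <- 32
  chk <- (outer(1:n, 1:n, `+`) %% 2) * 0.6 + 0.2
  f1 <- gray_to_rgb_for_test(chk)
  f2 <- gray_to_rgb_for_test(1 - chk)
  val <- motion_percentage(list(f1, f2, f1, f2), gaps = 1)
  expect_equal(val, edge_percentage(abs(f2 - f1))$percentage, tolerance = 1e-12)
})

test_that("motion percentage is symmetric under frame reversal", {
  frames <- make_fixture("moving_square_video", size = 64, n_frames = 8)
  val <- motion_percentage(frames, gaps = c(1, 3))
  rev_val <- motion_percentage(rev(frames), gaps = c(1, 3))
  expect_equal(val, rev_val, tolerance = 1e-12)
  expect_gt(val, 0)
})

test_that("TRON raises the motion score of a moving-square sequence", {
  frames <- make_fixture("moving_square_video", size = 96, n_frames = 6)
  raw <- motion_percentage(frames, gaps = 1:2)
  tp <- tron_params(0.1, diffusion_params(iterations = 3), 2)
  tron_frames <- lapply(frames, function(f) tron(f, tp))
  expect_gte(motion_percentage(tron_frames, gaps = 1:2), raw)
})
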