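test_that("retinal geometry arithmetic matches the physical constants", {
  expect_equal(fovea_px(retina_geometry(c(800, 800))), 20L)
  expect_equal(macula_px(retina_geometry(c(1008, 800))), 144)
  expect_equal(fovea_px(retina_geometry(c(1008, 800))), 24L)
  g <- retina_geometry(c(800, 800))
  expect_equal(macula_px(g), 800 * 6 / 42)
})

test_that("foveation passes the foveal patch through and blurs outward", {
  expect_error(foveate(matrix(0.5, 32, 32), fovea_xy = c(40, 2)), "outside")

  const <- matrix(0.5, 64, 64)
  expect_equal(foveate(const), const, tolerance = 1e-12)

  set.seed(17)
  img <- matrix(runif(256 * 256), 256, 256)
  out <- foveate(img, fovea_xy = c(128, 128))
  g <- retina_geometry(c(256, 256))
  half <- fovea_px(g) / 2
  patch <- (128 - half + 1):(128 + half)
  expect_identical(out[patch, patch], img[patch, patch])

  ring_var <- function(r) {
    cols <- (128 + half + r - 2):(128 + half + r + 2)
    stats::var(as.vector(out[109:148, cols]))
  }
  v_fovea <- stats::var(as.vector(out[patch, patch]))
  expect_lt(ring_var(100), ring_var(10))
  expect_lt(ring_var(10), v_fovea)
})

test_that("channel separation reproduces opponent semantics", {
  gray <- array(0.5, c(8, 8, 3))
  ch <- separate_channels(gray)
  expect_lt(max(abs(ch$gr_plane)), 1e-6)
  expect_lt(max(abs(ch$by_plane)), 1e-6)

  white <- array(1, c(4, 4, 3))
  expect_equal(separate_channels(white)$l_plane[1, 1], 100, tolerance = 1e-6)

  mk <- function(r, g, b) {
    x <- array(0, c(4, 4, 3)); x[, , 1] <- r; x[, , 2] <- g; x[, , 3] <- b; x
  }
  expect_lt(separate_channels(mk(0, 0, 1))$by_plane[1, 1], 0)  # blue
  expect_gt(separate_channels(mk(1, 1, 0))$by_plane[1, 1], 0)  # yellow
  expect_lt(separate_channels(mk(0, 1, 0))$gr_plane[1, 1], 0)  # green
  expect_gt(separate_channels(mk(1, 0, 0))$gr_plane[1, 1], 0)  # red
  expect_gt(separate_channels(mk(1, 0, 1))$gr_plane[1, 1], 0)  # magenta
  expect_equal(separate_channels(mk(0.2, 0.6, 0.4))$Y[1, 1], 0.4)
})

test_that("horizontal layer conserves mass and matches the erf step response", {
  gray <- separate_channels(array(0.5, c(16, 16, 3)))
  sm <- horizontal_layer(gray, sigma_h = 2)
  expect_equal(sm$R, gray$R, tolerance = 1e-9)

  imp <- array(0, c(33, 33, 3)); imp[17, 17, 1] <- 1
  chi <- horizontal_layer(separate_channels(imp), sigma_h = 2)
  expect_equal(sum(chi$R), 1, tolerance = 1e-6)  # unit-sum kernel conserves total

  # 10-90% rise distance of a Gaussian-blurred step: 2 * qnorm(0.9) * sigma
  n <- 64
  step <- array(0, c(n, n, 3))
  step[, 33:n, ] <- 1
  chs <- horizontal_layer(separate_channels(step), sigma_h = 2)
  profile <- chs$R[32, ]
  x10 <- stats::approx(profile, seq_len(n), xout = 0.1, ties = "ordered")$y
  x90 <- stats::approx(profile, seq_len(n), xout = 0.9, ties = "ordered")$y
  expect_equal(x90 - x10, 2 * stats::qnorm(0.9) * 2, tolerance = 0.1)
})

test_that("bipolar DoG nulls constants and produces a Mexican hat", {
  const <- matrix(0.3, 32, 32)
  expect_lt(max(abs(bipolar_dog(const, const))), 1e-9)

  # uniform centre, zero surround passes the centre constant through
  expect_equal(bipolar_dog(const, matrix(0, 32, 32)),
               const, tolerance = 1e-9)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  p <- dog_params(sigma_c = 1)
  resp <- bipolar_dog(imp, imp, p)
  # oracle: explicit kernel difference evaluated at the impulse
  kc <- naive_conv(imp, gaussian_kernel_for_test(1, 7))
  ks <- naive_conv(imp, gaussian_kernel_for_test(2, 35))
  expect_equal(resp, kc - ks, tolerance = 1e-9)
  expect_gt(resp[21, 21], 0)                      # positive centre peak
  expect_lt(resp[21, 26], 0)                      # negative annulus
  expect_lt(max(abs(resp[21, 21 + 18])), 1e-6)    # decays to zero
})

test_that("opponent signals vanish on achromatic input and sign red/green discs", {
  gray <- horizontal_layer(separate_channels(array(0.4, c(24, 24, 3))), 1)
  sig <- opponent_signals(gray)
  for (nm in c("l_on", "rg_map", "by_map")) expect_lt(max(abs(sig[[nm]])), 1e-9)

  img <- array(0, c(32, 32, 3))
  img[, , 2] <- 0.8                       # green background
  rr <- outer((1:32 - 16)^2, (1:32 - 16)^2, `+`) <= 36
  r_plane <- img[, , 1]; r_plane[rr] <- 0.9
  g_plane <- img[, , 2]; g_plane[rr] <- 0
  img[, , 1] <- r_plane; img[, , 2] <- g_plane
  sig2 <- opponent_signals(separate_channels(img))
  expect_gt(mean(sig2$rg_map[14:18, 14:18]), 0)     # red centre
  expect_lt(mean(sig2$rg_map[16, c(5, 27)]), 0)     # green side of boundary
})

test_that("Poisson reconstruction inverts its matched gradient exactly", {
  set.seed(23)
  base <- matrix(runif(24 * 24), 24, 24)
  img <- gaussian_blur_for_test(base, 2)
  rec <- reconstruct(reconstruction_gradient(img), mean_value = mean(img))
  expect_lt(sqrt(mean((rec - img)^2)), 1e-6)

  zero <- structure(list(gx = matrix(0, 8, 8), gy = matrix(0, 8, 8)),
                    class = "gradient_field")
  expect_lt(max(abs(reconstruct(zero, mean_value = 0.7) - 0.7)), 1e-12)

  bad <- structure(list(gx = matrix(Inf, 4, 4), gy = matrix(0, 4, 4)),
                   class = "gradient_field")
  expect_error(reconstruct(bad), "non-finite")
})

test_that("reconstruction is linear up to an additive constant", {
  set.seed(31)
  g1 <- reconstruction_gradient(gaussian_blur_for_test(matrix(runif(256), 16, 16), 1.5))
  g2 <- reconstruction_gradient(gaussian_blur_for_test(matrix(runif(256), 16, 16), 1.5))
  a <- 2.5; b <- -1.25
  comb <- structure(list(gx = a * g1$gx + b * g2$gx, gy = a * g1$gy + b * g2$gy),
                    class = "gradient_field")
  lhs <- reconstruct(comb)
  rhs <- a * reconstruct(g1) + b * reconstruct(g2)
  rhs <- rhs - mean(rhs)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("non-integrable fields get a least-squares solution", {
  h <- 16; w <- 16
  gx <- matrix(rep(seq_len(h), w), h, w)   # gx = row index: curl != 0
  gy <- matrix(0, h, w)
  field <- structure(list(gx = gx, gy = gy), class = "gradient_field")
  sol <- reconstruct(field)
  resid <- function(img) {
    g <- reconstruction_gradient(img)
    sum((g$gx - gx)^2 + (g$gy - gy)^2)
  }
  r_sol <- resid(sol)
  set.seed(5)
  for (i in 1:20) {
    cand <- gaussian_blur_for_test(matrix(runif(h * w, 0, 10), h, w), 1)
    expect_lte(r_sol, resid(cand) + 1e-9)
  }
})

test_that("scotoma masks hit the requested dead fraction deterministically", {
  g <- retina_geometry(c(128, 128))
  shp <- c(128L, 128L)
  expect_true(all(scotoma_mask(shp, scotoma_spec(c(64, 64), 1, 0), g) == 1))

  full <- scotoma_mask(shp, scotoma_spec(c(64, 64), 1, 1), g)
  dist2 <- outer((1:128 - 64)^2, (1:128 - 64)^2, `+`)
  disc <- dist2 <= (macula_px(g) / 2)^2
  expect_true(all(full[disc] == 0))
  expect_true(all(full[!disc] == 1))

  sp <- scotoma_spec(c(64, 64), 1, 0.5, seed = 77)
  m1 <- scotoma_mask(shp, sp, g)
  m2 <- scotoma_mask(shp, sp, g)
  expect_identical(m1, m2)
  frac <- sum(m1[disc] == 0) / sum(disc)
  expect_lt(abs(frac - 0.5), 0.02)
  expect_true(all(m1[!disc] == 1))
  expect_error(scotoma_spec(c(64, 64), -1, 0.5), "non-negative")
})

test_that("dead count is monotone in degeneration degree and scotoma size", {
  g <- retina_geometry(c(96, 96))
  shp <- c(96L, 96L)
  counts_d <- vapply(seq(0, 1, by = 0.2), function(d) {
    sum(scotoma_mask(shp, scotoma_spec(c(48, 48), 1, d, seed = 9), g) == 0)
  }, numeric(1))
  expect_true(all(diff(counts_d) >= 0))

  counts_s <- vapply(c(0.5, 1, 1.5, 2), function(s) {
    sum(scotoma_mask(shp, scotoma_spec(c(48, 48), s, 0.6, seed = 9), g) == 0)
  }, numeric(1))
  expect_true(all(diff(counts_s) >= 0))
})

test_that("degeneration fill reconstructs smooth structure from live pixels", {
  img <- matrix(0.5, 16, 16)
  ones <- matrix(1, 16, 16)
  expect_identical(apply_degeneration(img, ones), img)
  expect_error(apply_degeneration(img, matrix(0, 16, 16)), "entirely dead")

  # constant image with arbitrary mask stays constant
  set.seed(4)
  mask <- matrix(rbinom(256, 1, 0.6), 16, 16)
  mask[1, 1] <- 1
  out <- apply_degeneration(img, mask)
  expect_lt(max(abs(out - 0.5)), 1e-9)

  # checkerboard-dead ramp: equals the explicit normalized-convolution
  # oracle exactly, and interior fills stay within one ramp step
  n <- 8
  ramp <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n, byrow = TRUE)
  chk <- (outer(1:n, 1:n, `+`) %% 2)
  filled <- apply_degeneration(ramp, chk, sigma_fill = 1)
  expect_identical(filled[chk == 1], ramp[chk == 1])

  k <- gaussian_kernel_for_test(1, 7)
  num <- naive_conv(ramp * chk, k)
  den <- naive_conv(chk + 0, k)
  oracle <- ramp * chk + (num / den) * (1 - chk)
  expect_equal(filled, oracle, tolerance = 1e-9)

  step <- 1 / (n - 1)
  interior <- matrix(FALSE, n, n); interior[2:(n - 1), 2:(n - 1)] <- TRUE
  expect_lt(max(abs(filled - ramp)[chk == 0 & interior]), step)
})

test_that("the retina pipeline is identity-like on constants and deterministic", {
  img <- array(0.5, c(64, 64, 3))
  out <- retina_pipeline(img)
  expect_lt(max(abs(out - img)), 1 / 255)

  set.seed(6)
  nat <- array(runif(64 * 64 * 3), c(64, 64, 3))
  sp <- scotoma_spec(c(32, 32), 1, 1, seed = 3)
  o1 <- retina_pipeline(nat, c(32, 32), sp)
  o2 <- retina_pipeline(nat, c(32, 32), sp)
  expect_identical(o1, o2)
})

test_that("a full scotoma degrades the masked region more than the periphery", {
  set.seed(13)
  img <- fixture_scene_for_test(128)
  g <- retina_geometry(c(128, 128))
  sp <- scotoma_spec(c(64, 64), 1, 1, seed = 2)
  out <- retina_pipeline(img, c(64, 64), sp, geom = g)
  fov <- foveate(img, c(64, 64), g)

  dist2 <- outer((1:128 - 64)^2, (1:128 - 64)^2, `+`)
  disc <- dist2 <= (macula_px(g) / 2)^2
  rmse <- function(region) {
    d <- (luminance_for_test(out) - luminance_for_test(fov))[region]
    sqrt(mean(d^2))
  }
  ring <- dist2 > (macula_px(g))^2 & dist2 <= (2.5 * macula_px(g))^2
  expect_gt(rmse(disc), rmse(ring))
})

test_that("without a scotoma the pipeline preserves luminance structure", {
  set.seed(19)
  img <- fixture_scene_for_test(128, texture = 0.08)
  out <- retina_pipeline(img, c(64, 64), spec = NULL, sigma_h = 0.5,
                         dog = dog_params(sigma_c = 0.5))
  fov <- foveate(img, c(64, 64))
  r <- stats::cor(as.vector(luminance_for_test(out)),
                  as.vector(luminance_for_test(fov)))
  expect_gt(r, 0.9)
})
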