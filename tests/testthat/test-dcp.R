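test_that("fixed dark channel handles constants and matches the brute oracle", {
  const <- array(0, c(6, 6, 3))
  const[, , 1] <- 0.1; const[, , 2] <- 0.2; const[, , 3] <- 0.3
  expect_equal(dark_channel_fixed(const, 3), matrix(0.1, 6, 6),
               ignore_attr = TRUE)
  white <- array(1, c(5, 5, 3))
  expect_equal(dark_channel_fixed(white, 15), matrix(1, 5, 5),
               ignore_attr = TRUE)
  for (seed in 1:5) {
    img <- random_raster(seed, 8, 8)
    expect_equal(dark_channel_fixed(img, 3), brute_dark_channel(img, 3),
                 ignore_attr = TRUE)
    expect_equal(dark_channel_fixed(img, 7), brute_dark_channel(img, 7),
                 ignore_attr = TRUE)
  }
  expect_error(dark_channel_fixed(const, 4), class = "darklift_param_error")
})

test_that("dark channel counts one window application per pixel", {
  img <- random_raster(1, 10, 14)
  expect_identical(attr(dark_channel_fixed(img, 15), "n_windows"), 140L)
  cci <- compute_cci(to_grayscale(img), 3)
  expect_identical(attr(dark_channel_cci(img, cci), "n_windows"), 140L)
})

test_that("CCI-guided dark channel degenerates to fixed and is sandwiched", {
  for (seed in 1:4) {
    img <- random_raster(seed + 10, 12, 12)
    all7 <- matrix(7L, 12, 12)
    expect_equal(dark_channel_cci(img, all7), dark_channel_fixed(img, 15),
                 ignore_attr = TRUE)
    cci <- compute_cci(to_grayscale(img), 5)
    dc <- dark_channel_cci(img, cci)
    dc3 <- dark_channel_fixed(img, 3)
    dc15 <- dark_channel_fixed(img, 15)
    expect_true(all(dc15 <= dc + 1e-12))
    expect_true(all(dc <= dc3 + 1e-12))
    # per-pixel agreement with a direct window lookup
    for (k in unique(as.vector(cci))) {
      sel <- cci == k
      ref <- brute_dark_channel(img, 2L * k + 1L)
      expect_equal(dc[sel], ref[sel])
    }
  }
  img <- random_raster(3, 6, 6)
  expect_error(dark_channel_cci(img, matrix(7L, 5, 5)),
               class = "darklift_param_error")
})

test_that("dark channel windows nest: larger patches never increase it", {
  img <- random_raster(21, 16, 16)
  sizes <- seq(3L, 15L, 2L)
  dcs <- lapply(sizes, function(s) dark_channel_fixed(img, s))
  for (i in seq_along(sizes)[-1]) {
    expect_true(all(dcs[[i]] <= dcs[[i - 1]] + 1e-12))
  }
  ch_min <- pmin(img[, , 1], img[, , 2], img[, , 3])
  expect_true(all(dcs[[1]] <= ch_min + 1e-12))
})

test_that("atmospheric light selects the brightest dark-channel pixels", {
  v <- array(0.4, c(6, 6, 3))
  expect_equal(estimate_atmospheric_light(v, dark_channel_fixed(v, 3), 0.002),
               c(0.4, 0.4, 0.4))

  # planted bright white block on a dark background: a small fraction
  # selects only block positions
  img <- array(0.05, c(20, 20, 3))
  img[8:12, 8:12, ] <- 1
  dc <- dark_channel_fixed(img, 3)
  A <- estimate_atmospheric_light(img, dc, 0.002)  # ceiling(0.8) = 1 pixel
  expect_equal(A, c(1, 1, 1))
  A9 <- estimate_atmospheric_light(img, dc, 9 / 400)
  expect_equal(A9, c(1, 1, 1))

  # fraction = 1 averages everything
  rnd <- random_raster(9, 10, 10)
  A_all <- estimate_atmospheric_light(rnd, dark_channel_fixed(rnd, 3), 1)
  expect_equal(A_all, apply(rnd, 3, mean))

  expect_error(estimate_atmospheric_light(rnd, dark_channel_fixed(rnd, 3), 0),
               class = "darklift_param_error")
})

test_that("transmission follows 1 - omega * windowed min ratio, clamped", {
  # region equal to A gives t = 1 - omega
  img <- array(0, c(12, 12, 3))
  A <- c(0.8, 0.7, 0.6)
  for (ch in 1:3) img[, , ch] <- A[ch]
  cci <- matrix(3L, 12, 12)
  expect_equal(transmission_map(img, A, cci, 0.9), matrix(0.1, 12, 12),
               tolerance = 1e-12)

  # a zero channel anywhere in the window forces t = 1 there
  img2 <- random_raster(2, 9, 9)
  img2[5, 5, 2] <- 0
  tm <- transmission_map(img2, c(0.9, 0.9, 0.9), matrix(1L, 9, 9), 0.9)
  expect_equal(tm[5, 5], 1)
  expect_equal(tm[4, 4], 1)

  # omega = 0 preserves all haze
  expect_equal(transmission_map(img2, A, matrix(7L, 9, 9), 0),
               matrix(1, 9, 9))

  # bounds: t in [1 - omega, 1] whenever img <= A channelwise
  img3 <- random_raster(3, 10, 10) * 0.6
  tm3 <- transmission_map(img3, c(0.6, 0.6, 0.6), compute_cci(
    to_grayscale(img3), 3), 0.9)
  expect_true(all(tm3 >= 0.1 - 1e-12 & tm3 <= 1))

  expect_error(transmission_map(img2, c(0, 0.5, 0.5), matrix(1L, 9, 9), 0.9),
               class = "darklift_degenerate_airlight")
})

test_that("radiance recovery inverts the hazy-image model", {
  img <- random_raster(4, 8, 8)
  A <- c(0.9, 0.85, 0.8)

  # t == 1 is the identity
  expect_equal(recover_radiance(img, matrix(1, 8, 8), A, 0.1, clamp = FALSE),
               img)

  # pixels equal to A recover to A for any t
  flatA <- array(0, c(4, 4, 3))
  for (ch in 1:3) flatA[, , ch] <- A[ch]
  out <- recover_radiance(flatA, matrix(0.37, 4, 4), A, 0.1)
  expect_equal(out, flatA)

  # exact forward-inverse round trip with the true t and A
  set.seed(5)
  J <- random_raster(5, 10, 10)
  tf <- matrix(runif(100, 0.25, 0.95), 10, 10)
  hazy <- apply_haze(J, tf, A)
  back <- recover_radiance(hazy, tf, A, t0 = 0.1, clamp = FALSE)
  expect_lt(max(abs(back - J)), 1e-12)
})
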