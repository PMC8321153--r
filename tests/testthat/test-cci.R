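test_that("local sigma is zero on constant images and rejects bad window sizes", {
  for (ps in c(3L, 9L, 15L)) {
    expect_equal(local_sigma(matrix(0.42, 10, 14), ps), matrix(0, 10, 14))
  }
  g <- random_gray(1, 8, 8)
  expect_error(local_sigma(g, 4), class = "darklift_param_error")
  expect_error(local_sigma(g, 17), class = "darklift_param_error")
  expect_error(local_sigma(g, 1), class = "darklift_param_error")
})

test_that("local sigma matches the brute-force per-window oracle", {
  for (seed in 1:5) {
    g <- random_gray(seed, 11, 13)
    for (ps in c(3L, 7L, 15L)) {
      expect_equal(local_sigma(g, ps), brute_sigma(g, ps), tolerance = 1e-9)
    }
  }
})

test_that("local sigma obeys the two-point closed form on a checkerboard", {
  # interior 3x3 windows of a 0/1 unit checkerboard hold k ones out of 9;
  # the population sd of a two-point {0,1} sample is sqrt(p(1-p))
  g <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)
  s <- local_sigma(g, 3)
  expect_equal(s[6, 6], sqrt((4 / 9) * (5 / 9)), tolerance = 1e-12)
  expect_equal(s[6, 7], sqrt((5 / 9) * (4 / 9)), tolerance = 1e-12)
})

test_that("sigma stack layers equal independent local_sigma calls", {
  g <- random_gray(7, 16, 12)
  st <- sigma_stack(g)
  expect_equal(dim(st), c(16L, 12L, 7L))
  for (k in 1:7) {
    expect_identical(st[, , k], local_sigma(g, 2L * k + 1L))
  }
  expect_true(all(is.finite(st)) && min(st) >= 0)
  expect_equal(sigma_stack(matrix(0.5, 6, 6)), array(0, c(6, 6, 7)))
})

test_that("code-to-size mapping is 2c+1 over the full span", {
  expect_identical(patch_size_from_code(1L), 3L)
  expect_identical(patch_size_from_code(4L), 9L)
  expect_identical(patch_size_from_code(7L), 15L)
  expect_identical(patch_size_from_code(1:7), seq(3L, 15L, 2L))
  expect_error(patch_size_from_code(0L), class = "darklift_param_error")
  expect_error(patch_size_from_code(8L), class = "darklift_param_error")
})

test_that("constant images select code 7 everywhere, at any tolerance", {
  for (tol in c(0, 3, 7, 50)) {
    expect_identical(compute_cci(matrix(0.3, 9, 9), tol), matrix(7L, 9, 9))
  }
})

test_that("a sigma ratio straddling the compounded threshold flips code 7 to 1", {
  # all intermediate sizes share the incumbent sigma, so only the direct
  # 7 -> 1 jump is in play; at t = 5 the boundary ratio is 0.95^6
  make_stack <- function(ratio) {
    st <- array(1, c(1, 1, 7))
    st[1, 1, 1] <- ratio
    st
  }
  thr <- tolerance_acceptance_factor(5, 7L, 1L)
  expect_identical(cci_from_sigmas(make_stack(0.73), 5), matrix(1L, 1, 1))
  expect_identical(cci_from_sigmas(make_stack(0.74), 5), matrix(7L, 1, 1))
  expect_identical(cci_from_sigmas(make_stack(thr * (1 - 1e-9)), 5),
                   matrix(1L, 1, 1))
  expect_identical(cci_from_sigmas(make_stack(thr * (1 + 1e-9)), 5),
                   matrix(7L, 1, 1))
})

test_that("code selection matches the argmin oracle on random images", {
  for (seed in 1:6) {
    g <- random_gray(seed + 100, 16, 16)
    st <- sigma_stack(g)
    for (tol in c(0, 3, 5, 10)) {
      expect_identical(cci_from_sigmas(st, tol), brute_cci(st, tol))
    }
  }
})

test_that("with t=0 the stored code attains the minimal sigma, ties to larger", {
  for (seed in 1:4) {
    g <- random_gray(seed + 40, 14, 14)
    st <- sigma_stack(g)
    cci <- cci_from_sigmas(st, 0)
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(ncol(g))) {
        expect_equal(st[i, j, cci[i, j]], min(st[i, j, ]))
      }
    }
  }
})

test_that("raising the tolerance never decreases any pixel's code", {
  tols <- c(0, 1, 3, 5, 7, 10, 20)
  for (seed in 1:5) {
    g <- random_gray(seed + 60, 16, 16)
    st <- sigma_stack(g)
    prev <- cci_from_sigmas(st, tols[1])
    for (tol in tols[-1]) {
      cur <- cci_from_sigmas(st, tol)
      expect_true(all(cur >= prev))
      prev <- cur
    }
  }
})

test_that("flat regions take code 7 and textured regions take small codes", {
  sc <- textured_lowlight_scene()
  cci <- compute_cci(to_grayscale(invert(sc$low)), 3)
  bg <- mask_core(sc$masks$background)
  tex <- mask_core(sc$masks$texture)
  expect_true(all(cci[bg] == 7L))
  expect_gt(mean(cci[tex] <= 2L), 0.5)
})

test_that("code histogram counts every code and reports the non-3x3 share", {
  cci <- matrix(c(1L, 1L, 7L, 4L), 2, 2)
  h <- cci_code_histogram(cci)
  expect_equal(unname(h$counts), c(2L, 0L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(h$non3x3_share, 0.5)
  expect_equal(sum(h$share), 1)
})

test_that("the compounded acceptance factor follows (1 - t/100)^steps", {
  expect_equal(tolerance_acceptance_factor(5, 7L, 1L), 0.95^6)
  expect_equal(tolerance_acceptance_factor(0, 7L, 1L), 1)
  expect_equal(tolerance_acceptance_factor(7, 5L, 2L), 0.93^3)
  expect_error(tolerance_acceptance_factor(5, 1L, 7L),
               class = "darklift_param_error")
})
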