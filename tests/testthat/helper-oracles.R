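# Brute-force reference implementations used as independent oracles.
# They share the edge-replication window semantics of the package operators
# but compute everything by direct per-window enumeration.

win_vals <- function(x, i, j, r) {
  ri <- pmin(pmax((i - r):(i + r), 1L), nrow(x))
  ci <- pmin(pmax((j - r):(j + r), 1L), ncol(x))
  x[ri, ci]
}

brute_sigma <- function(gray, patch_size) {
  r <- (patch_size - 1L) %/% 2L
  out <- matrix(0, nrow(gray), ncol(gray))
  for (i in seq_len(nrow(gray))) {
    for (j in seq_len(ncol(gray))) {
      v <- win_vals(gray, i, j, r)
      out[i, j] <- sqrt(mean((v - mean(v))^2))
    }
  }
  out
}

brute_dark_channel <- function(img, patch_size) {
  r <- (patch_size - 1L) %/% 2L
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j] <- min(win_vals(img[, , 1], i, j, r),
                       win_vals(img[, , 2], i, j, r),
                       win_vals(img[, , 3], i, j, r))
    }
  }
  out
}

# code selection as a direct minimisation of sigma_k * (1 - t/100)^k over
# the seven layers, ties resolved toward the largest code
brute_cci <- function(sigmas, tolerance_pct) {
  f <- 1 - tolerance_pct / 100
  H <- dim(sigmas)[1]; W <- dim(sigmas)[2]
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      g <- sigmas[i, j, ] * f^(1:7)
      out[i, j] <- max(which(g == min(g)))
    }
  }
  out
}

brute_guided <- function(guide, src, radius, eps) {
  H <- nrow(guide); W <- ncol(guide)
  a <- matrix(0, H, W); b <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      vi <- win_vals(guide, i, j, radius)
      vp <- win_vals(src, i, j, radius)
      var_i <- mean((vi - mean(vi))^2)
      cov_ip <- mean(vi * vp) - mean(vi) * mean(vp)
      a[i, j] <- cov_ip / (var_i + eps)
      b[i, j] <- mean(vp) - a[i, j] * mean(vi)
    }
  }
  q <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      q[i, j] <- mean(win_vals(a, i, j, radius)) * guide[i, j] +
        mean(win_vals(b, i, j, radius))
    }
  }
  list(a = a, b = b, q = q)
}

random_gray <- function(seed, h = 12L, w = 12L) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

random_raster <- function(seed, h = 12L, w = 12L) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3L))
}
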