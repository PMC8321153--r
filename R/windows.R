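# Windowed primitives shared by the contrast, dark-channel and guided-filter
# code.  All operators use edge replication so every pixel sees a full-size
# window; cost is independent of the window radius for the box filter and
# linear in the radius for the sliding minimum.

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("darklift_param_error", "error")))
}

check_matrix <- function(x, what = "input") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1L || ncol(x) < 1L) {
    stop_param(what, " must be a non-empty numeric matrix")
  }
  invisible(x)
}

check_radius <- function(r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r != round(r)) {
    stop_param("radius must be a single non-negative integer")
  }
  as.integer(r)
}

# patch_size -> radius, validating oddness
patch_radius <- function(patch_size, min_size = 1L, max_size = Inf) {
  if (length(patch_size) != 1L || is.na(patch_size) ||
      patch_size != round(patch_size) || patch_size %% 2 != 1 ||
      patch_size < min_size || patch_size > max_size) {
    stop_param("patch_size must be a single odd integer in [", min_size,
               ", ", max_size, "], got ", patch_size)
  }
  as.integer((patch_size - 1L) / 2L)
}

pad_replicate <- function(x, r) {
  if (r == 0L) return(x)
  ri <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
  ci <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
  x[ri, ci, drop = FALSE]
}

# Mean over the (2r+1)x(2r+1) window centred at each pixel, replicated
# borders.  Integral-image formulation: O(H*W) regardless of r.
box_mean <- function(x, r) {
  check_matrix(x)
  r <- check_radius(r)
  if (r == 0L) return(x)
  p <- pad_replicate(x, r)
  ii <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  ii[-1L, -1L] <- p
  ii <- apply(ii, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  H <- nrow(x); W <- ncol(x)
  k <- 2L * r + 1L
  rows_hi <- seq_len(H) + k; rows_lo <- seq_len(H)
  cols_hi <- seq_len(W) + k; cols_lo <- seq_len(W)
  s <- ii[rows_hi, cols_hi, drop = FALSE] - ii[rows_lo, cols_hi, drop = FALSE] -
       ii[rows_hi, cols_lo, drop = FALSE] + ii[rows_lo, cols_lo, drop = FALSE]
  s / (k * k)
}

# Minimum over the (2r+1)x(2r+1) window centred at each pixel, replicated
# borders.  Separable: a row pass then a column pass of clamped shifts.
min_filter <- function(x, r) {
  check_matrix(x)
  r <- check_radius(r)
  if (r == 0L) return(x)
  H <- nrow(x); W <- ncol(x)
  out <- x
  for (off in c(seq_len(r), -seq_len(r))) {
    idx <- pmin.int(pmax.int(seq_len(H) + off, 1L), H)
    out <- pmin(out, x[idx, , drop = FALSE])
  }
  y <- out
  for (off in c(seq_len(r), -seq_len(r))) {
    idx <- pmin.int(pmax.int(seq_len(W) + off, 1L), W)
    out <- pmin(out, y[, idx, drop = FALSE])
  }
  out
}

# Bilinear resize with pixel-centre alignment; clamped at the borders.
resize_bilinear <- function(x, new_h, new_w) {
  check_matrix(x)
  H <- nrow(x); W <- ncol(x)
  if (new_h < 1L || new_w < 1L) stop_param("target size must be >= 1")
  if (new_h == H && new_w == W) return(x)
  yc <- (seq_len(new_h) - 0.5) * (H / new_h) + 0.5
  xc <- (seq_len(new_w) - 0.5) * (W / new_w) + 0.5
  y0 <- pmin.int(pmax.int(floor(yc), 1), H)
  x0 <- pmin.int(pmax.int(floor(xc), 1), W)
  y1 <- pmin.int(y0 + 1L, H)
  x1 <- pmin.int(x0 + 1L, W)
  wy <- matrix(pmin(pmax(yc - y0, 0), 1), new_h, new_w)
  wx <- matrix(pmin(pmax(xc - x0, 0), 1), new_h, new_w, byrow = TRUE)
  top <- x[y0, x0, drop = FALSE] * (1 - wx) + x[y0, x1, drop = FALSE] * wx
  bot <- x[y1, x0, drop = FALSE] * (1 - wx) + x[y1, x1, drop = FALSE] * wx
  top * (1 - wy) + bot * wy
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# zero-filled shift used by the edge detector
shift_mat <- function(x, dy, dx, fill = 0) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dy; cs <- seq_len(W) - dx
  keep_r <- rs >= 1L & rs <= H
  keep_c <- cs >= 1L & cs <= W
  out[which(keep_r), which(keep_c)] <- x[rs[keep_r], cs[keep_c], drop = FALSE]
  out
}
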