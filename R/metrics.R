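#' @title Blind enhancement metrics
#'
#' @description
#' No-reference scores for judging an enhancement without ground truth:
#' the e-score (relative increase in visible-edge count between original
#' and enhanced image), the r-score (geometric mean of gradient-magnitude
#' ratios at visible edges, a visibility level), and the Global Contrast
#' Factor (a multi-resolution average of local contrasts).
#'
#' @name metrics
NULL

stop_metric <- function(...) {
  stop(errorCondition(paste0(...), class = c("darklift_metric_error",
                                             "error")))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with edge replication
conv_sep <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_along(k)) {
    idx <- pmin.int(pmax.int(seq_len(H) + (i - 1L - r), 1L), H)
    out <- out + k[i] * x[idx, , drop = FALSE]
  }
  x2 <- out
  out <- matrix(0, H, W)
  for (i in seq_along(k)) {
    idx <- pmin.int(pmax.int(seq_len(W) + (i - 1L - r), 1L), W)
    out <- out + k[i] * x2[, idx, drop = FALSE]
  }
  out
}

# 3x3 convolution with edge replication; kern indexed [dy+2, dx+2]
conv3 <- function(x, kern) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (dy in -1:1) {
    ridx <- pmin.int(pmax.int(seq_len(H) + dy, 1L), H)
    for (dx in -1:1) {
      kv <- kern[dy + 2L, dx + 2L]
      if (kv == 0) next
      cidx <- pmin.int(pmax.int(seq_len(W) + dx, 1L), W)
      out <- out + kv * x[ridx, cidx, drop = FALSE]
    }
  }
  out
}

SOBEL_X <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
SOBEL_Y <- t(SOBEL_X)

#' Sobel gradient magnitude
#'
#' @param gray `H x W` matrix.
#' @return `H x W` matrix of gradient magnitudes (edge-replicated borders).
#' @export
sobel_magnitude <- function(gray) {
  check_matrix(gray, "gray")
  gx <- conv3(gray, SOBEL_X)
  gy <- conv3(gray, SOBEL_Y)
  sqrt(gx * gx + gy * gy)
}

#' Canny edge map
#'
#' Gaussian smoothing (sigma = sqrt(2)), Sobel gradients, four-direction
#' non-maximum suppression and hysteresis thresholding.  The two thresholds
#' apply to the gradient magnitude normalized by its maximum, so they are
#' fractions in `(0, 1)`.
#'
#' @param gray `H x W` matrix in `[0, 1]`.
#' @param strong upper hysteresis threshold (default 0.2).
#' @param weak lower hysteresis threshold (default 0.05).
#' @param sigma Gaussian smoothing scale in pixels.
#' @return `H x W` logical matrix of edge pixels.
#' @export
canny_edges <- function(gray, strong = 0.2, weak = 0.05, sigma = sqrt(2)) {
  check_gray(gray)
  if (!(weak > 0 && strong > weak && strong < 1)) {
    stop_param("thresholds must satisfy 0 < weak < strong < 1")
  }
  sm <- conv_sep(gray, gaussian_kernel_1d(sigma))
  gx <- conv3(sm, SOBEL_X)
  gy <- conv3(sm, SOBEL_Y)
  mag <- sqrt(gx * gx + gy * gy)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
  mag <- mag / mx

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- integer(length(ang))
  sector[(ang < 22.5) | (ang >= 157.5)] <- 0L   # horizontal gradient
  sector[ang >= 22.5 & ang < 67.5] <- 1L
  sector[ang >= 67.5 & ang < 112.5] <- 2L       # vertical gradient
  sector[ang >= 112.5 & ang < 157.5] <- 3L
  dim(sector) <- dim(mag)
  nbr <- list(
    `0` = list(c(0L, 1L), c(0L, -1L)),
    `1` = list(c(1L, 1L), c(-1L, -1L)),
    `2` = list(c(1L, 0L), c(-1L, 0L)),
    `3` = list(c(1L, -1L), c(-1L, 1L))
  )
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    n1 <- shift_mat(mag, nbr[[s + 1L]][[1]][1], nbr[[s + 1L]][[1]][2])
    n2 <- shift_mat(mag, nbr[[s + 1L]][[2]][1], nbr[[s + 1L]][[2]][2])
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  nms <- mag
  nms[!keep] <- 0

  # hysteresis: strong seeds, grow into weak pixels 8-connectedly
  strong_map <- nms > strong
  weak_map <- nms > weak
  edges <- strong_map
  repeat {
    grown <- edges
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      grown <- grown | (shift_mat(edges, dy, dx) > 0)
    }
    grown <- grown & weak_map
    grown <- grown | edges
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' e-score: relative increase in visible edges
#'
#' Counts Canny edge pixels in the original and the enhanced image and
#' returns `(n_enh - n_orig) / n_orig`.  Positive values mean the
#' enhancement made more edges visible.
#'
#' @param orig,enh `H x W` grayscale images in `[0, 1]`, same dimensions.
#' @param strong,weak Canny hysteresis thresholds (defaults 0.2 and 0.05).
#' @return the e-score (dimensionless).  The edge counts are attached as
#'   attributes `edges_before` and `edges_after`.
#' @export
e_score <- function(orig, enh, strong = 0.2, weak = 0.05) {
  check_gray(orig, "orig"); check_gray(enh, "enh")
  if (!all(dim(orig) == dim(enh))) stop_param("images must share dimensions")
  n0 <- sum(canny_edges(orig, strong, weak))
  n1 <- sum(canny_edges(enh, strong, weak))
  if (n0 == 0L) {
    stop_metric("e-score undefined: no visible edges in the original image")
  }
  structure((n1 - n0) / n0, edges_before = n0, edges_after = n1)
}

#' r-score: visibility level from gradient ratios
#'
#' Geometric mean, over the edge pixels visible in the enhanced image, of
#' the ratio of Sobel gradient magnitudes (enhanced over original).  Pixels
#' with zero original gradient are excluded.  A value of 2 means gradients
#' at visible edges are on average twice as strong after enhancement.
#'
#' @inheritParams e_score
#' @return the r-score (> 0).
#' @export
r_score <- function(orig, enh, strong = 0.2, weak = 0.05) {
  check_gray(orig, "orig"); check_gray(enh, "enh")
  if (!all(dim(orig) == dim(enh))) stop_param("images must share dimensions")
  edges <- canny_edges(enh, strong, weak)
  g0 <- sobel_magnitude(orig)
  g1 <- sobel_magnitude(enh)
  sel <- edges & g0 > 0 & g1 > 0
  if (!any(sel)) {
    stop_metric("r-score undefined: no visible edges with nonzero gradient")
  }
  exp(mean(log(g1[sel] / g0[sel])))
}

# Global Contrast Factor constants from its published definition: gamma-2.2
# linearization, perceptual luminance L = 100*sqrt(l), 9 halved resolutions
# combined with the weight polynomial below.
GCF_LEVELS <- 9L
gcf_weight <- function(i) {
  (-0.406385 * i / 9 + 0.334573) * i / 9 + 0.0877526
}

halve_image <- function(x) {
  H2 <- nrow(x) %/% 2L; W2 <- ncol(x) %/% 2L
  x <- x[seq_len(2L * H2), seq_len(2L * W2), drop = FALSE]
  (x[seq(1L, 2L * H2, 2L), seq(1L, 2L * W2, 2L), drop = FALSE] +
   x[seq(2L, 2L * H2, 2L), seq(1L, 2L * W2, 2L), drop = FALSE] +
   x[seq(1L, 2L * H2, 2L), seq(2L, 2L * W2, 2L), drop = FALSE] +
   x[seq(2L, 2L * H2, 2L), seq(2L, 2L * W2, 2L), drop = FALSE]) / 4
}

mean_local_contrast <- function(lum) {
  H <- nrow(lum); W <- ncol(lum)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  if (W >= 2L) {
    d <- abs(lum[, -1L, drop = FALSE] - lum[, -W, drop = FALSE])
    acc[, -W] <- acc[, -W] + d; cnt[, -W] <- cnt[, -W] + 1
    acc[, -1L] <- acc[, -1L] + d; cnt[, -1L] <- cnt[, -1L] + 1
  }
  if (H >= 2L) {
    d <- abs(lum[-1L, , drop = FALSE] - lum[-H, , drop = FALSE])
    acc[-H, ] <- acc[-H, ] + d; cnt[-H, ] <- cnt[-H, ] + 1
    acc[-1L, ] <- acc[-1L, ] + d; cnt[-1L, ] <- cnt[-1L, ] + 1
  }
  if (all(cnt == 0)) return(0)
  mean((acc / pmax(cnt, 1))[cnt > 0])
}

#' Global Contrast Factor
#'
#' Average absolute luminance difference to the 4-neighbours (on a
#' gamma-linearized perceptual luminance scale), computed at nine
#' progressively halved resolutions and combined with a fixed
#' resolution-weighting polynomial.  Zero for a constant image; larger
#' values mean more perceived contrast.
#'
#' @param gray `H x W` grayscale image in `[0, 1]`.
#' @return the GCF (>= 0).
#' @export
gcf <- function(gray) {
  check_gray(gray)
  lin <- gray^2.2
  total <- 0
  cur <- lin
  for (i in seq_len(GCF_LEVELS)) {
    lum <- 100 * sqrt(cur)
    total <- total + gcf_weight(i) * mean_local_contrast(lum)
    if (nrow(cur) < 2L || ncol(cur) < 2L) break
    cur <- halve_image(cur)
  }
  total
}

#' Full metric report for an original/enhanced pair
#'
#' @param orig,enh `H x W x 3` colour images (converted to grayscale
#'   internally) or `H x W` grayscale matrices.
#' @param strong,weak Canny hysteresis thresholds.
#' @return list with `e_score`, `r_score`, `gcf_before`, `gcf_after`,
#'   `edge_count_before`, `edge_count_after`, plus nullable slots
#'   (`surf`, `bliinds2`, `fade`) reserved for externally computed scores.
#' @export
metric_report <- function(orig, enh, strong = 0.2, weak = 0.05) {
  g0 <- if (is.matrix(orig)) orig else to_grayscale(orig)
  g1 <- if (is.matrix(enh)) enh else to_grayscale(enh)
  e <- e_score(g0, g1, strong, weak)
  list(
    e_score = as.numeric(e),
    r_score = r_score(g0, g1, strong, weak),
    gcf_before = gcf(g0),
    gcf_after = gcf(g1),
    edge_count_before = attr(e, "edges_before"),
    edge_count_after = attr(e, "edges_after"),
    surf = NULL, bliinds2 = NULL, fade = NULL
  )
}
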