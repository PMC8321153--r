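#' @title Guided filter and its subsampled fast variant
#'
#' @description
#' The guided filter expresses the output as a locally affine function of a
#' guidance image: within each window `w_k` of radius `r`,
#' `q_i = a_k I_i + b_k`, with
#' `a_k = (mean(I p) - mean(I) mean(p)) / (var(I) + eps)` and
#' `b_k = mean(p) - a_k mean(I)`.  Averaging the coefficients over all
#' windows containing a pixel yields `q_i = abar_i I_i + bbar_i`.  Applied
#' to a raw transmission map with the hazy image as guide, it transfers
#' scene edges into the map and removes the blocky window artifacts that
#' cause halos.  All box means use edge replication and integral images, so
#' a filter pass costs O(H*W) regardless of the radius.
#'
#' @name guided_filter
NULL

#' Guided-filter parameter set
#'
#' @param radius full-resolution square window radius `r` (default 28).
#' @param eps smoothing degree `eps > 0` on the squared normalized-intensity
#'   scale (default 0.45); larger values push the output toward a plain box
#'   blur of the source.
#' @param subsample subsampling ratio `s >= 1` for the fast variant
#'   (default 4); `s = 1` disables subsampling.
#' @return list with class `gf_params`.
#' @export
gf_params <- function(radius = 28L, eps = 0.45, subsample = 4L) {
  if (length(radius) != 1L || is.na(radius) || radius < 1 ||
      radius != round(radius)) {
    stop_param("radius must be an integer >= 1")
  }
  if (length(eps) != 1L || is.na(eps) || eps <= 0) {
    stop_param("eps must be > 0")
  }
  if (length(subsample) != 1L || is.na(subsample) || subsample < 1 ||
      subsample != round(subsample)) {
    stop_param("subsample must be an integer >= 1")
  }
  structure(list(radius = as.integer(radius), eps = eps,
                 subsample = as.integer(subsample)),
            class = "gf_params")
}

gf_coefficients <- function(guide, src, radius, eps) {
  m_i <- box_mean(guide, radius)
  m_p <- box_mean(src, radius)
  corr_ip <- box_mean(guide * src, radius)
  corr_ii <- box_mean(guide * guide, radius)
  var_i <- corr_ii - m_i * m_i
  cov_ip <- corr_ip - m_i * m_p
  a <- cov_ip / (var_i + eps)
  b <- m_p - a * m_i
  list(a = a, b = b)
}

#' Guided filter at full resolution
#'
#' @param guide `H x W` guidance image.
#' @param src `H x W` source map to be filtered.
#' @param params a [gf_params()] object; `subsample` is ignored here.
#' @return `H x W` filtered map.
#' @export
guided_filter <- function(guide, src, params = gf_params()) {
  check_matrix(guide, "guide")
  check_matrix(src, "src")
  if (!all(dim(guide) == dim(src))) {
    stop_param("guide and src must have identical dimensions")
  }
  cf <- gf_coefficients(guide, src, params$radius, params$eps)
  box_mean(cf$a, params$radius) * guide + box_mean(cf$b, params$radius)
}

#' Fast guided filter with subsampling
#'
#' Both guide and source are subsampled by the ratio `s` (bilinear), the
#' coefficient maps are computed at the reduced scale with radius
#' `max(1, round(r / s))`, their window means are up-sampled bilinearly to
#' full size, and combined as `abar * guide + bbar`.  With `s = 1` the
#' computation is exactly [guided_filter()].
#'
#' @inheritParams guided_filter
#' @return `H x W` filtered map.
#' @export
fast_guided_filter <- function(guide, src, params = gf_params()) {
  check_matrix(guide, "guide")
  check_matrix(src, "src")
  if (!all(dim(guide) == dim(src))) {
    stop_param("guide and src must have identical dimensions")
  }
  s <- params$subsample
  if (s == 1L) return(guided_filter(guide, src, params))
  H <- nrow(guide); W <- ncol(guide)
  if (s > min(H, W) / 2) {
    stop_param("subsample ratio ", s, " too large for a ", H, " x ", W,
               " image")
  }
  h2 <- max(1L, as.integer(round(H / s)))
  w2 <- max(1L, as.integer(round(W / s)))
  g_sub <- resize_bilinear(guide, h2, w2)
  p_sub <- resize_bilinear(src, h2, w2)
  r_sub <- max(1L, as.integer(round(params$radius / s)))
  cf <- gf_coefficients(g_sub, p_sub, r_sub, params$eps)
  a_bar <- resize_bilinear(box_mean(cf$a, r_sub), H, W)
  b_bar <- resize_bilinear(box_mean(cf$b, r_sub), H, W)
  a_bar * guide + b_bar
}

#' Refine a transmission map
#'
#' Runs the fast guided filter on a raw transmission map, guided by the
#' grayscale of the hazy image, and re-clamps to `[0, 1]`.
#'
#' @param tmap raw `H x W` transmission map.
#' @param guide `H x W` grayscale guidance image (the hazy image).
#' @param params a [gf_params()] object.
#' @return refined `H x W` transmission in `[0, 1]`.
#' @export
refine_transmission <- function(tmap, guide, params = gf_params()) {
  clamp01(fast_guided_filter(guide, tmap, params))
}
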