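#' @title Dark channel, atmospheric light, transmission, radiance
#'
#' @description
#' The hazy-image model is `I(x) = J(x) t(x) + A (1 - t(x))`: observed
#' intensity `I` mixes the scene radiance `J` with a global atmospheric
#' light `A`, weighted by the transmission `t` (the fraction of scene light
#' reaching the camera).  The dark channel — the windowed minimum over
#' space and colour channels — is near zero for haze-free regions, which
#' lets `A` and `t` be estimated from a single image and `J` recovered by
#' inverting the model.
#'
#' @name dcp
NULL

# min over the three channels at each pixel
channel_min <- function(img) {
  pmin(img[, , 1], img[, , 2], img[, , 3])
}

#' Dark channel with a fixed window size
#'
#' Per pixel, the minimum intensity over the three colour channels and over
#' the square window centred at the pixel (edge-replicated borders).  The
#' returned matrix carries an `n_windows` attribute counting window
#' applications (one per pixel), the bookkeeping used when comparing static
#' and adaptive patch strategies.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param patch_size odd window size >= 1.
#' @return `H x W` matrix in `[0, 1]` with attribute `n_windows`.
#' @export
dark_channel_fixed <- function(img, patch_size) {
  check_raster(img)
  r <- patch_radius(patch_size)
  dc <- min_filter(channel_min(img), r)
  attr(dc, "n_windows") <- nrow(dc) * ncol(dc)
  dc
}

#' Dark channel with per-pixel window sizes from a contrast code image
#'
#' Identical to [dark_channel_fixed()] except that the window size at each
#' pixel is `patch_size_from_code(cci[pixel])`.  Because windows are nested,
#' the result lies pointwise between the 15x15 and 3x3 fixed dark channels.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param cci `H x W` integer matrix of codes in 1..7.
#' @return `H x W` matrix in `[0, 1]` with attribute `n_windows`.
#' @export
dark_channel_cci <- function(img, cci) {
  check_raster(img)
  check_cci(cci)
  if (!all(dim(cci) == dim(img)[1:2])) {
    stop_param("cci dimensions must match the image")
  }
  dc <- select_by_code(channel_min(img), cci, min_filter)
  attr(dc, "n_windows") <- nrow(dc) * ncol(dc)
  dc
}

# Apply a windowed operator at each of the code-selected radii and pick the
# per-pixel result; only codes present in the CCI are computed.
select_by_code <- function(x, cci, op) {
  out <- matrix(0, nrow(x), ncol(x))
  for (k in sort(unique(as.vector(cci)))) {
    sel <- cci == k
    yk <- op(x, k)  # radius k <-> window 2k+1
    out[sel] <- yk[sel]
  }
  out
}

#' Estimate the global atmospheric light
#'
#' Selects the `ceiling(fraction * H * W)` brightest dark-channel positions
#' (at least one; ties broken by row-major scan order) and returns the
#' per-channel mean of the hazy image over those positions.
#'
#' @param img `H x W x 3` hazy image in `[0, 1]`.
#' @param dc its dark channel, `H x W`.
#' @param fraction fraction of pixels to select, in `(0, 1]`; default 0.002
#'   (the 0.2% brightest).
#' @return numeric length-3 vector `A` with components in `[0, 1]`.
#' @export
estimate_atmospheric_light <- function(img, dc, fraction = 0.002) {
  check_raster(img)
  check_matrix(dc, "dc")
  if (!all(dim(dc) == dim(img)[1:2])) {
    stop_param("dark channel dimensions must match the image")
  }
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 ||
      fraction > 1) {
    stop_param("fraction must be in (0, 1]")
  }
  H <- nrow(dc); W <- ncol(dc)
  n <- max(1L, ceiling(fraction * H * W))
  dcv <- as.vector(t(dc))                      # row-major linearization
  ord <- order(dcv, decreasing = TRUE)         # stable: ties by scan order
  idx0 <- ord[seq_len(n)] - 1L
  rows <- idx0 %/% W + 1L
  cols <- idx0 %% W + 1L
  a <- vapply(1:3, function(ch) mean(img[cbind(rows, cols, ch)]), numeric(1))
  a
}

#' Transmission map with contrast-guided windows
#'
#' Per pixel, `t(x) = 1 - omega * min over the window of (min_c I_c / A_c)`,
#' the window size taken from the contrast code image; clamped to `[0, 1]`.
#' `omega` in `[0, 1]` controls how much haze is removed: `omega = 1`
#' removes all detected haze, `omega = 0` preserves it entirely (`t == 1`).
#'
#' @param img `H x W x 3` hazy image in `[0, 1]`.
#' @param A length-3 atmospheric light, all components > 0.
#' @param cci `H x W` integer matrix of codes in 1..7.
#' @param omega haze-removal strength in `[0, 1]`; default 0.9.
#' @return `H x W` transmission matrix in `[0, 1]`.
#' @export
transmission_map <- function(img, A, cci, omega = 0.9) {
  check_raster(img)
  check_cci(cci)
  if (!all(dim(cci) == dim(img)[1:2])) {
    stop_param("cci dimensions must match the image")
  }
  if (length(A) != 3L || anyNA(A) || any(A <= 0) || any(A > 1)) {
    stop(errorCondition(
      "atmospheric light must be three components in (0, 1]",
      class = c("darklift_degenerate_airlight", "darklift_param_error",
                "error")))
  }
  if (length(omega) != 1L || is.na(omega) || omega < 0 || omega > 1) {
    stop_param("omega must be in [0, 1]")
  }
  ratio <- pmin(img[, , 1] / A[1], img[, , 2] / A[2], img[, , 3] / A[3])
  tmap <- 1 - omega * select_by_code(ratio, cci, min_filter)
  clamp01(tmap)
}

#' Recover scene radiance from the hazy image model
#'
#' Inverts `I = J t + A (1 - t)` as `J = (I - A) / max(t, t0) + A`, per
#' pixel and channel.  `t0` bounds the denominator away from zero so that
#' haze-dense (low-`t`) regions do not blow up the recovered intensities.
#'
#' @param img `H x W x 3` hazy image in `[0, 1]`.
#' @param tmap `H x W` transmission in `[0, 1]`.
#' @param A length-3 atmospheric light.
#' @param t0 lower bound for the denominator, in `(0, 1]`; default 0.1.
#' @param clamp clamp the result to `[0, 1]` (default); set `FALSE` to get
#'   the raw algebraic inverse, e.g. for round-trip checks against a known
#'   ground-truth radiance.
#' @return `H x W x 3` recovered radiance.
#' @export
recover_radiance <- function(img, tmap, A, t0 = 0.1, clamp = TRUE) {
  check_raster(img)
  check_matrix(tmap, "tmap")
  if (!all(dim(tmap) == dim(img)[1:2])) {
    stop_param("transmission dimensions must match the image")
  }
  if (length(t0) != 1L || is.na(t0) || t0 <= 0 || t0 > 1) {
    stop_param("t0 must be in (0, 1]")
  }
  if (length(A) != 3L || anyNA(A) || min(A) < 0 || max(A) > 1) {
    stop_param("atmospheric light must be three components in [0, 1]")
  }
  denom <- pmax(tmap, t0)
  out <- img
  for (ch in 1:3) {
    out[, , ch] <- (img[, , ch] - A[ch]) / denom + A[ch]
  }
  if (clamp) out <- clamp01(out)
  out
}
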