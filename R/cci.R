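#' @title Contrast code image
#'
#' @description
#' The contrast code image (CCI) stores, for every pixel, an integer code
#' `c` in 1..7 selecting the window size `2c + 1` (3x3 up to 15x15) that the
#' dark-channel and transmission operators use at that pixel.  The code is
#' chosen by comparing the local standard deviation of the (inverted,
#' grayscale) image across the seven candidate sizes: low sigma marks a
#' homogeneous region where a large window strengthens the dark channel
#' prior; high sigma marks texture or edges where a small window avoids
#' halos.  A tolerance parameter biases the choice toward larger windows.
#'
#' @name cci
NULL

# candidate window sizes are 3,5,...,15 <-> codes 1..7
N_CODES <- 7L

# sigma values below this (on the [0,1] intensity scale) are treated as an
# exact zero.  The integral-image box sums accumulate rounding of order
# 1e-10 in the variance on large images, which the square root inflates to
# ~1e-5 sigma on perfectly flat regions; genuine 8-bit contrast is >= 1/255,
# three orders of magnitude above the guard, so only numerically-flat
# regions are affected — and those must keep the code-7 preference.
SIGMA_EPS <- 1e-5

#' Local standard deviation over a square window
#'
#' Per-pixel population standard deviation (divisor `N`) of the intensities
#' inside the `patch_size x patch_size` window centred at the pixel, with
#' edge replication at the borders.
#'
#' @param gray `H x W` matrix in `[0, 1]`.
#' @param patch_size odd window size in 3..15.
#' @return `H x W` matrix of standard deviations (>= 0).
#' @export
local_sigma <- function(gray, patch_size) {
  check_gray(gray)
  r <- patch_radius(patch_size, min_size = 3L, max_size = 15L)
  mu <- box_mean(gray, r)
  m2 <- box_mean(gray * gray, r)
  s <- sqrt(pmax(m2 - mu * mu, 0))
  s[s < SIGMA_EPS] <- 0
  s
}

#' Standard deviations for all seven candidate window sizes
#'
#' @param gray `H x W` matrix in `[0, 1]`.
#' @return `H x W x 7` array; layer `k` holds [local_sigma()] at window size
#'   `2k + 1`.
#' @export
sigma_stack <- function(gray) {
  check_gray(gray)
  out <- array(0, c(nrow(gray), ncol(gray), N_CODES))
  for (k in seq_len(N_CODES)) {
    out[, , k] <- local_sigma(gray, 2L * k + 1L)
  }
  out
}

#' Window size selected by a contrast code
#'
#' @param code integer code(s) in 1..7.
#' @return odd window size(s) `2 * code + 1`.
#' @export
patch_size_from_code <- function(code) {
  if (length(code) < 1L || anyNA(code) || any(code != round(code)) ||
      any(code < 1L) || any(code > N_CODES)) {
    stop_param("code must be integer(s) in 1..", N_CODES)
  }
  as.integer(2L * code + 1L)
}

#' Contrast code image from a sigma stack
#'
#' Every pixel starts at code 7 (the 15x15 window).  Candidate codes are then
#' scanned from 6 down to 1; candidate `c` displaces the current best code
#' `b` iff
#' \deqn{\sigma_c < \sigma_b \, (1 - t/100)^{\,b - c}}
#' i.e. the candidate's sigma must undercut the incumbent's by the tolerance
#' percentage `t`, compounded once per code step.  With `t = 0` this selects
#' the minimal-sigma window, ties going to the larger one.  The scan is
#' algebraically equivalent to minimising \eqn{\sigma_k (1 - t/100)^k} over
#' `k` (ties toward large `k`), which is the form used by the test oracles.
#'
#' @param sigmas `H x W x 7` array from [sigma_stack()].
#' @param tolerance_pct tolerance `t` in percent, `0 <= t < 100`.
#' @return `H x W` integer matrix of codes in 1..7.
#' @export
cci_from_sigmas <- function(sigmas, tolerance_pct = 3) {
  if (!is.array(sigmas) || length(dim(sigmas)) != 3L ||
      dim(sigmas)[3] != N_CODES || min(sigmas) < 0) {
    stop_param("sigmas must be a non-negative H x W x 7 array")
  }
  check_tolerance(tolerance_pct)
  f <- 1 - tolerance_pct / 100
  best_code <- matrix(N_CODES, dim(sigmas)[1], dim(sigmas)[2])
  best_sig <- sigmas[, , N_CODES]
  for (cand in (N_CODES - 1L):1L) {
    sc <- sigmas[, , cand]
    accept <- sc < best_sig * f^(best_code - cand)
    best_sig[accept] <- sc[accept]
    best_code[accept] <- cand
  }
  storage.mode(best_code) <- "integer"
  best_code
}

check_tolerance <- function(tolerance_pct) {
  if (length(tolerance_pct) != 1L || is.na(tolerance_pct) ||
      tolerance_pct < 0 || tolerance_pct >= 100) {
    stop_param("tolerance_pct must be a single value in [0, 100)")
  }
  invisible(tolerance_pct)
}

#' Compute the contrast code image of a grayscale image
#'
#' Convenience wrapper: [sigma_stack()] followed by [cci_from_sigmas()].
#' In the enhancement pipeline the input is the grayscale of the inverted
#' (hazy) image; sigma is invariant under inversion, so the codes are the
#' same either way.
#'
#' @inheritParams local_sigma
#' @inheritParams cci_from_sigmas
#' @return `H x W` integer matrix of codes in 1..7.
#' @export
compute_cci <- function(gray, tolerance_pct = 3) {
  cci_from_sigmas(sigma_stack(gray), tolerance_pct)
}

#' Compounded tolerance acceptance factor
#'
#' The factor `(1 - t/100)^(code_from - code_to)` that a candidate window's
#' sigma must undercut, relative to the incumbent's sigma, for the candidate
#' code `code_to` to displace the incumbent `code_from` in one jump.  With a
#' 5% tolerance, moving from the 15x15 window (code 7) straight to the 3x3
#' window (code 1) requires the sigma ratio to fall below
#' `0.95^6 = 0.7351` — i.e. the small window's sigma must be at most 73.51%
#' of the large window's.
#'
#' @param tolerance_pct tolerance in percent.
#' @param code_from incumbent code (larger window).
#' @param code_to candidate code (smaller window).
#' @return the acceptance factor in `(0, 1]`.
#' @export
tolerance_acceptance_factor <- function(tolerance_pct, code_from = 7L,
                                        code_to = 1L) {
  check_tolerance(tolerance_pct)
  patch_size_from_code(code_from)
  patch_size_from_code(code_to)
  if (code_to > code_from) stop_param("code_to must be <= code_from")
  (1 - tolerance_pct / 100)^(code_from - code_to)
}

#' Histogram of contrast codes
#'
#' Counts and shares of each code 1..7, plus the share of pixels whose
#' selected window is larger than 3x3 (the statistic used to report how the
#' tolerance shifts selections toward bigger windows).
#'
#' @param cci `H x W` integer matrix of codes.
#' @return list with `counts` (named integer vector over codes 1..7),
#'   `share` (fractions) and `non3x3_share`.
#' @export
cci_code_histogram <- function(cci) {
  check_cci(cci)
  counts <- tabulate(cci, nbins = N_CODES)
  names(counts) <- paste0(2L * seq_len(N_CODES) + 1L, "x",
                          2L * seq_len(N_CODES) + 1L)
  list(
    counts = counts,
    share = counts / length(cci),
    non3x3_share = 1 - counts[[1]] / length(cci)
  )
}

check_cci <- function(cci, what = "cci") {
  check_matrix(cci, what)
  if (anyNA(cci) || any(cci != round(cci)) || min(cci) < 1 ||
      max(cci) > N_CODES) {
    stop_param(what, " entries must be integer codes in 1..", N_CODES)
  }
  invisible(cci)
}

#' Write a contrast code image as a debug PNG
#'
#' Codes are scaled by 36 (so code 7 maps to intensity 252/255) for
#' visibility in an 8-bit single-channel PNG.
#'
#' @param cci `H x W` integer matrix of codes.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_cci_debug <- function(cci, path) {
  check_cci(cci)
  png::writePNG(cci * 36 / 255, path)
  invisible(path)
}
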