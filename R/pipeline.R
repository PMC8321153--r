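#' @title End-to-end enhancement pipeline
#'
#' @description
#' Full contrast-guided enhancement of a low-light image: invert, compute
#' the contrast code image on the inverted grayscale, build the
#' contrast-guided dark channel, estimate the atmospheric light, estimate
#' the transmission map, refine it with the fast guided filter, recover the
#' radiance and invert back.
#'
#' @name pipeline
NULL

#' Enhancement parameter set
#'
#' Defaults reproduce the reference configuration: `omega = 0.9`,
#' `tolerance_pct = 3`, `t0 = 0.1`, `airlight_fraction = 0.002` and guided
#' filter `radius = 28`, `eps = 0.45`, `subsample = 4`.
#'
#' @param omega haze-removal strength in `[0, 1]`.
#' @param tolerance_pct contrast-code tolerance in percent.
#' @param t0 transmission lower bound in `(0, 1]`.
#' @param airlight_fraction fraction of brightest dark-channel pixels used
#'   for the atmospheric light, in `(0, 1]`.
#' @param gf a [gf_params()] object.
#' @return list with class `enhance_params`.
#' @export
enhance_params <- function(omega = 0.9, tolerance_pct = 3, t0 = 0.1,
                           airlight_fraction = 0.002, gf = gf_params()) {
  if (omega < 0 || omega > 1) stop_param("omega must be in [0, 1]")
  check_tolerance(tolerance_pct)
  if (t0 <= 0 || t0 > 1) stop_param("t0 must be in (0, 1]")
  if (airlight_fraction <= 0 || airlight_fraction > 1) {
    stop_param("airlight_fraction must be in (0, 1]")
  }
  if (!inherits(gf, "gf_params")) stop_param("gf must be a gf_params object")
  structure(list(omega = omega, tolerance_pct = tolerance_pct, t0 = t0,
                 airlight_fraction = airlight_fraction, gf = gf),
            class = "enhance_params")
}

#' Enhance a low-light image
#'
#' Stages, in order: invert; grayscale; contrast code image; contrast-guided
#' dark channel; atmospheric light; transmission map; fast-guided-filter
#' refinement; radiance recovery; final inversion.  Deterministic for fixed
#' input and parameters.  A degenerate all-black input inverts to all-white,
#' yielding `A = (1,1,1)` and `t = 1 - omega` everywhere; the pipeline
#' proceeds normally and clamps.
#'
#' @param img `H x W x 3` low-light image in `[0, 1]`.
#' @param params an [enhance_params()] object.
#' @param patch_size optional odd window size in 3..15; when given, the
#'   adaptive contrast code image is replaced by this constant window
#'   (static-patch mode, used for comparisons).
#' @param refine logical; apply the guided-filter refinement to the
#'   transmission map (default `TRUE`).  With `FALSE` the raw map is used,
#'   which exposes the halo artifacts the refinement suppresses.
#' @return list with class `enhancement_result`: `enhanced`, `cci`,
#'   `dark_channel`, `transmission_raw`, `transmission_refined`,
#'   `airlight`, `params`.
#' @export
enhance <- function(img, params = enhance_params(), patch_size = NULL,
                    refine = TRUE) {
  check_raster(img)
  if (!inherits(params, "enhance_params")) {
    stop_param("params must be an enhance_params object")
  }
  inv <- invert(img)
  gray <- to_grayscale(inv)
  cci <- if (is.null(patch_size)) {
    compute_cci(gray, params$tolerance_pct)
  } else {
    code <- (patch_radius(patch_size, 3L, 15L))
    matrix(as.integer(code), nrow(gray), ncol(gray))
  }
  dc <- dark_channel_cci(inv, cci)
  A <- estimate_atmospheric_light(inv, dc, params$airlight_fraction)
  A <- pmax(A, 1e-6)  # guard Eq.-3 divisor on pathological inputs
  t_raw <- transmission_map(inv, A, cci, params$omega)
  t_ref <- if (refine) refine_transmission(t_raw, gray, params$gf) else t_raw
  J <- recover_radiance(inv, t_ref, A, params$t0)
  structure(list(
    enhanced = invert(J),
    cci = cci,
    dark_channel = dc,
    transmission_raw = t_raw,
    transmission_refined = t_ref,
    airlight = A,
    params = params
  ), class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  d <- dim(x$enhanced)
  hist <- cci_code_histogram(x$cci)
  cat("Contrast-guided enhancement result\n")
  cat(sprintf("  image: %d x %d\n", d[1], d[2]))
  cat(sprintf("  airlight: (%.3f, %.3f, %.3f)\n", x$airlight[1],
              x$airlight[2], x$airlight[3]))
  cat(sprintf("  transmission (refined): [%.3f, %.3f]\n",
              min(x$transmission_refined), max(x$transmission_refined)))
  cat(sprintf("  non-3x3 code share: %.1f%%\n", 100 * hist$non3x3_share))
  invisible(x)
}

#' Write the staged intermediates of an enhancement
#'
#' Dumps the contrast code image (scaled for visibility), dark channel and
#' both transmission maps as 8-bit grayscale PNGs.
#'
#' @param result an [enhance()] result.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return the directory, invisibly.
#' @export
write_intermediates <- function(result, dir, prefix = "stage") {
  if (!inherits(result, "enhancement_result")) {
    stop_param("result must be an enhancement_result")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cci_debug(result$cci, file.path(dir, paste0(prefix, "_cci.png")))
  png::writePNG(clamp01(result$dark_channel),
                file.path(dir, paste0(prefix, "_dark_channel.png")))
  png::writePNG(result$transmission_raw,
                file.path(dir, paste0(prefix, "_transmission_raw.png")))
  png::writePNG(result$transmission_refined,
                file.path(dir, paste0(prefix, "_transmission_refined.png")))
  invisible(dir)
}
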