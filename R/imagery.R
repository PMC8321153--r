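#' @title Image containers and intensity conventions
#'
#' @description
#' Images are plain numeric arrays.  A colour image is an `H x W x 3` array
#' with channels ordered R, G, B; a grayscale image is an `H x W` matrix.
#' All intensities are real values in `[0, 1]`: 8-bit files are mapped to
#' this scale on read and back to 8-bit on write.  Every pipeline stage
#' clamps its output to `[0, 1]` on exit.
#'
#' @name imagery
NULL

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("darklift_io_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("darklift_format_error", "error")))
}

#' Validate a colour image array
#'
#' @param img object to check.
#' @param what label used in error messages.
#' @return `img`, invisibly, if it is a valid `H x W x 3` numeric array with
#'   finite values in `[0, 1]`.
#' @keywords internal
check_raster <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      !is.numeric(img) || dim(img)[1] < 1L || dim(img)[2] < 1L) {
    stop_param(what, " must be an H x W x 3 numeric array")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    stop_param(what, " intensities must be finite and within [0, 1]")
  }
  invisible(img)
}

check_gray <- function(img, what = "gray") {
  check_matrix(img, what)
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    stop_param(what, " intensities must be finite and within [0, 1]")
  }
  invisible(img)
}

#' Invert an image
#'
#' Maps every intensity `v` to `1 - v` (the normalized form of the 8-bit
#' complement `255 - x`).  Inversion turns darkness in a low-light image
#' into haze, so that a dehazing pipeline applied to the inverted image
#' brightens the dark regions of the original.  The map is an involution:
#' `invert(invert(img))` is bit-identical to `img`.
#'
#' @param img `H x W x 3` array or `H x W` matrix with values in `[0, 1]`.
#' @return The inverted image, same shape as the input.
#' @examples
#' x <- array(runif(48), c(4, 4, 3))
#' stopifnot(identical(invert(invert(x)), x))
#' @export
invert <- function(img) {
  if (is.matrix(img)) check_gray(img) else check_raster(img)
  1 - img
}

# ITU-R BT.601 luminance weights; they sum to exactly 1 so that grayscale
# conversion commutes with inversion.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Convert a colour image to grayscale
#'
#' Weighted luminance with ITU-R BT.601 weights (0.299, 0.587, 0.114).
#' Because the weights sum to one, `to_grayscale(invert(x))` equals
#' `1 - to_grayscale(x)` elementwise, which makes local standard deviation
#' (an affine-invariant) identical on the original and inverted image.
#'
#' @param img `H x W x 3` array with values in `[0, 1]`.
#' @return `H x W` matrix of luminance values in `[0, 1]`.
#' @export
to_grayscale <- function(img) {
  check_raster(img)
  g <- LUMA_WEIGHTS[1] * img[, , 1] + LUMA_WEIGHTS[2] * img[, , 2] +
    LUMA_WEIGHTS[3] * img[, , 3]
  clamp01(g)
}

file_ext_lower <- function(path) {
  tolower(sub(".*\\.", "", basename(path)))
}

#' Read an 8-bit image file
#'
#' Supports PNG, JPEG and TIFF.  Grayscale files are promoted to three
#' identical channels; an alpha channel is dropped with a warning.  Only
#' 8-bit-per-channel files are accepted.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff` file.
#' @return `H x W x 3` numeric array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_param("path must be a single file path")
  }
  if (!file.exists(path)) stop_io("cannot read image: no such file: ", path)
  ext <- file_ext_lower(path)
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path, info = TRUE),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      tif = ,
      tiff = tiff::readTIFF(path, info = TRUE),
      stop_format("unsupported image format: .", ext,
                  " (supported: png, jpg, jpeg, tif, tiff)")
    ),
    error = function(e) {
      if (inherits(e, "darklift_format_error")) stop(e)
      stop_format("failed to decode ", path, ": ", conditionMessage(e))
    }
  )
  info <- attributes(raw)
  depth <- info$info$bit.depth %||% info$bits.per.sample %||% 8L
  if (!all(depth == 8L)) {
    stop_format("unsupported bit depth ", paste(depth, collapse = "/"),
                " in ", path, " (only 8-bit per channel is supported)")
  }
  arr <- unclass(raw)
  attributes(arr) <- list(dim = dim(raw))
  if (is.null(dim(arr))) dim(arr) <- c(length(arr), 1L)
  if (length(dim(arr)) == 2L) {
    arr <- array(arr, c(dim(arr), 3L))
  } else if (dim(arr)[3] == 2L) {           # gray + alpha
    warning("dropping alpha channel in ", path)
    arr <- array(arr[, , 1], c(dim(arr)[1:2], 3L))
  } else if (dim(arr)[3] == 4L) {           # rgb + alpha
    warning("dropping alpha channel in ", path)
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (dim(arr)[3] == 1L) {
    arr <- array(arr[, , 1], c(dim(arr)[1:2], 3L))
  }
  if (dim(arr)[3] != 3L) {
    stop_format("unsupported channel count ", dim(arr)[3], " in ", path)
  }
  clamp01(arr)
}

#' Write an image to an 8-bit file
#'
#' The container format follows the file extension (PNG, JPEG, TIFF).  PNG
#' and TIFF round-trip 8-bit data losslessly.
#'
#' @param img `H x W x 3` array or `H x W` matrix in `[0, 1]`.
#' @param path output path; the extension selects the codec.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) check_gray(img) else check_raster(img)
  ext <- file_ext_lower(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("output directory does not exist: ", dir)
  # quantize to the 8-bit grid so that write/read round-trips exactly
  q <- round(img * 255) / 255
  switch(ext,
    png = png::writePNG(q, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(q, path, quality = 0.95),
    tif = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    stop_format("unsupported output format: .", ext)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
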