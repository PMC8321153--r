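#' @title Synthetic low-light scene generator
#'
#' @description
#' Deterministic scenes with known ground truth for every pipeline stage:
#' a clean radiance image assembled from flat patches, textured squares and
#' planted bright blocks (emulating dark homogeneous seafloor plus bright
#' structured apparatus), a named transmission field, and an atmospheric
#' light.  Hazy and low-light observations are composed through the forward
#' model `I = J t + A (1 - t)` (low-light images via the inversion duality),
#' so recovery can be checked against the planted truth.
#'
#' @name synthfix
NULL

stop_spec <- function(...) {
  stop(errorCondition(paste0(...), class = c("darklift_spec_error", "error")))
}

#' Describe a synthetic scene
#'
#' @param seed integer seed controlling all randomness in the scene.
#' @param height,width image dimensions in pixels.
#' @param background background radiance intensity in `[0, 1]`.
#' @param regions list of region descriptors.  Each is a list with `type`
#'   (`"flat"`, `"texture"` or `"block"`), pixel bounds `rows = c(r0, r1)`
#'   and `cols = c(c0, c1)`, and type-specific fields: `intensity` for flat
#'   patches and blocks; `base`, `amplitude` and `kind`
#'   (`"checker"` with `period`, or `"noise"`) for textures.
#' @param airlight length-3 atmospheric light in `(0, 1]`.
#' @param t_field named transmission pattern: a list with `type` one of
#'   `"constant"` (`value`), `"ramp"` (`from`, `to`, left-to-right),
#'   `"radial"` (`centre_value`, `edge_value`) or `"blockwise"` (`nblocks`,
#'   `range = c(lo, hi)`, values drawn per block from the scene seed).
#' @return list with class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, height = 64L, width = 64L,
                       background = 0.15, regions = list(),
                       airlight = c(0.85, 0.9, 0.95),
                       t_field = list(type = "constant", value = 0.7)) {
  if (height < 1L || width < 1L) stop_spec("scene dimensions must be >= 1")
  if (background < 0 || background > 1) {
    stop_spec("background intensity must be in [0, 1]")
  }
  if (length(airlight) != 3L || any(airlight <= 0) || any(airlight > 1)) {
    stop_spec("airlight must be three components in (0, 1]")
  }
  occupied <- matrix(FALSE, height, width)
  for (rg in regions) {
    if (is.null(rg$type) || is.null(rg$rows) || is.null(rg$cols)) {
      stop_spec("each region needs type, rows and cols")
    }
    if (rg$rows[1] < 1L || rg$rows[2] > height || rg$cols[1] < 1L ||
        rg$cols[2] > width || rg$rows[1] > rg$rows[2] ||
        rg$cols[1] > rg$cols[2]) {
      stop_spec("region bounds outside the image")
    }
    sel <- occupied[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2]]
    if (any(sel)) stop_spec("regions must not overlap")
    occupied[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2]] <- TRUE
  }
  structure(list(seed = as.integer(seed), height = as.integer(height),
                 width = as.integer(width), background = background,
                 regions = regions, airlight = airlight, t_field = t_field),
            class = "scene_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

smooth_noise <- function(h, w, radius = 1L) {
  box_mean(matrix(stats::runif(h * w, -1, 1), h, w), radius)
}

#' Render the clean radiance of a scene
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`H x W x 3` radiance in `[0, 1]`) and `masks`
#'   (named list of logical matrices: `background`, `flat`, `texture`,
#'   `block`, plus `region_<i>` per region).  Deterministic for a fixed
#'   seed.
#' @export
make_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_spec("spec must be a scene_spec")
  H <- spec$height; W <- spec$width
  gray <- matrix(spec$background, H, W)
  masks <- list(
    background = matrix(TRUE, H, W),
    flat = matrix(FALSE, H, W),
    texture = matrix(FALSE, H, W),
    block = matrix(FALSE, H, W)
  )
  with_seed(spec$seed, {
    for (i in seq_along(spec$regions)) {
      rg <- spec$regions[[i]]
      rows <- rg$rows[1]:rg$rows[2]; cols <- rg$cols[1]:rg$cols[2]
      patch <- switch(rg$type,
        flat = matrix(rg$intensity, length(rows), length(cols)),
        block = matrix(rg$intensity %||% 1, length(rows), length(cols)),
        texture = {
          base <- rg$base %||% 0.5
          amp <- rg$amplitude %||% 0.4
          kind <- rg$kind %||% "checker"
          if (kind == "checker") {
            p <- rg$period %||% 2L
            ph <- (outer(rows, cols, function(r, co) {
              (r %/% p + co %/% p) %% 2
            }))
            base + amp * (2 * ph - 1) / 2
          } else {
            base + amp * smooth_noise(length(rows), length(cols))
          }
        },
        stop_spec("unknown region type: ", rg$type)
      )
      gray[rows, cols] <- clamp01(patch)
      m <- matrix(FALSE, H, W); m[rows, cols] <- TRUE
      masks[[rg$type]] <- masks[[rg$type]] | m
      masks$background <- masks$background & !m
      masks[[paste0("region_", i)]] <- m
    }
  })
  list(image = array(rep(gray, 3L), c(H, W, 3L)), masks = masks)
}

#' Render the transmission field of a scene
#'
#' @param spec a [scene_spec()].
#' @return `H x W` matrix with values in `[0, 1]`.
#' @export
make_t_field <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_spec("spec must be a scene_spec")
  H <- spec$height; W <- spec$width
  tf <- spec$t_field
  tm <- switch(tf$type,
    constant = matrix(tf$value, H, W),
    ramp = matrix(rep(seq(tf$from, tf$to, length.out = W), each = H), H, W),
    radial = {
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      d <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`))
      d <- d / max(d)
      tf$centre_value + (tf$edge_value - tf$centre_value) * d
    },
    blockwise = with_seed(spec$seed + 1L, {
      nb <- tf$nblocks %||% 4L
      vals <- matrix(stats::runif(nb * nb, tf$range[1], tf$range[2]), nb, nb)
      ri <- pmin.int(ceiling(seq_len(H) / H * nb), nb)
      ci <- pmin.int(ceiling(seq_len(W) / W * nb), nb)
      vals[ri, ci, drop = FALSE]
    }),
    stop_spec("unknown t_field type: ", tf$type)
  )
  if (min(tm) < 0 || max(tm) > 1) stop_spec("t_field values must be in [0, 1]")
  tm
}

#' Compose a hazy observation from radiance, transmission and airlight
#'
#' Forward model `I = J t + A (1 - t)`, per pixel and channel.
#'
#' @param J `H x W x 3` clean radiance in `[0, 1]`.
#' @param t_field `H x W` transmission in `[0, 1]`.
#' @param A length-3 atmospheric light in `[0, 1]`.
#' @return `H x W x 3` hazy image in `[0, 1]`.
#' @export
apply_haze <- function(J, t_field, A) {
  check_raster(J, "J")
  check_matrix(t_field, "t_field")
  if (!all(dim(t_field) == dim(J)[1:2])) {
    stop_spec("t_field dimensions must match the radiance image")
  }
  if (min(t_field) < 0 || max(t_field) > 1) {
    stop_spec("t_field values must be in [0, 1]")
  }
  if (length(A) != 3L || min(A) < 0 || max(A) > 1) {
    stop_spec("airlight must be three components in [0, 1]")
  }
  out <- J
  for (ch in 1:3) {
    out[, , ch] <- J[, , ch] * t_field + A[ch] * (1 - t_field)
  }
  clamp01(out)
}

#' Compose a low-light observation via the inversion duality
#'
#' Returns `invert(apply_haze(invert(J), t, A))`: a low-light image whose
#' inverted version carries exactly the planted haze, so the enhancement
#' pipeline (which inverts, dehazes, re-inverts) can be validated against
#' the clean radiance `J`.
#'
#' @inheritParams apply_haze
#' @return `H x W x 3` low-light image in `[0, 1]`.
#' @export
make_lowlight <- function(J, t_field, A) {
  invert(apply_haze(invert(J), t_field, A))
}
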