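# Shared synthetic-scene builders for the pipeline-level tests.

# Bright flat block on a dark flat background under a left-to-right
# transmission ramp: a clean step-edge scene whose enhancement exposes halo
# artifacts next to the block.  Fully deterministic.
step_edge_scene <- function(scale = 1) {
  H <- as.integer(round(160 * scale)); W <- as.integer(round(240 * scale))
  r0 <- as.integer(round(60 * scale)); r1 <- as.integer(round(110 * scale))
  c0 <- as.integer(round(90 * scale)); c1 <- as.integer(round(170 * scale))
  sp <- scene_spec(
    seed = 11, height = H, width = W, background = 0.15,
    regions = list(list(type = "flat", rows = c(r0, r1), cols = c(c0, c1),
                        intensity = 0.9)),
    airlight = c(0.9, 0.9, 0.9),
    t_field = list(type = "ramp", from = 0.35, to = 0.85)
  )
  sc <- make_scene(sp)
  low <- make_lowlight(sc$image, make_t_field(sp), sp$airlight)
  list(low = low, bg = sc$masks$background, H = H, W = W,
       block_rows = c(r0, r1), block_cols = c(c0, c1))
}

# Mean absolute deviation of the enhanced intensity in a band adjacent to
# the block edge, relative to the same-column far-field level.  The
# transmission ramp varies only along columns, so within a column the
# far-field background is constant and any band deviation is an edge
# artifact (halo).
halo_band_dev <- function(enhanced, s, band) {
  g <- to_grayscale(enhanced)
  near <- matrix(FALSE, s$H, s$W)
  near[pmax(1, s$block_rows[1] - band):pmin(s$H, s$block_rows[2] + band),
       pmax(1, s$block_cols[1] - band):pmin(s$W, s$block_cols[2] + band)] <-
    TRUE
  near <- near & s$bg
  far <- s$bg & !near
  devs <- numeric(0)
  for (j in unique(which(near, arr.ind = TRUE)[, 2])) {
    if (!any(far[, j])) next
    ref <- stats::median(g[far[, j], j])
    devs <- c(devs, abs(g[near[, j], j] - ref))
  }
  mean(devs)
}

# Low-light scene with a flat background and one noise-textured square,
# under a constant transmission field: the canonical regionality fixture
# (homogeneous seafloor + structured apparatus).
textured_lowlight_scene <- function(seed = 9, h = 96L, w = 96L) {
  rows <- round(c(0.26, 0.73) * h)
  cols <- round(c(0.26, 0.73) * w)
  sp <- scene_spec(
    seed = seed, height = h, width = w, background = 0.2,
    regions = list(list(type = "texture", rows = rows, cols = cols,
                        base = 0.5, amplitude = 0.5, kind = "noise")),
    t_field = list(type = "constant", value = 0.6)
  )
  sc <- make_scene(sp)
  low <- make_lowlight(sc$image, make_t_field(sp), sp$airlight)
  list(low = low, masks = sc$masks, spec = sp)
}

# mask eroded so that no 15x15 window centred inside it crosses the border
mask_core <- function(mask, radius = 8L) {
  darklift:::min_filter(mask * 1, radius) == 1
}
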