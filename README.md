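# darklift

Contrast-guided enhancement of low-light underwater images in R.

Deep-sea imagery is usually lit by artificial sources, so large parts of
every frame sit in darkness that hides fish, invertebrates and scientific
apparatus.  `darklift` brightens such images with a dehazing trick: in the
inverted image `x̄ = 255 − x`, darkness looks like haze, so removing that
haze and inverting back illuminates the dark regions while preserving
structure.

## The method

The hazy-image model is

    I(x) = J(x) t(x) + A (1 − t(x))

with observed image `I`, scene radiance `J`, global atmospheric light `A`
and transmission `t(x) ∈ [0,1]`.  The Dark Channel Prior (DCP) — the
windowed minimum over space and colour channels of a haze-free image is
near zero — gives the classical single-image estimates

    t(x) = 1 − ω · min_{y∈Ω(x)} ( min_c I_c(y) / A_c ),
    J(x) = (I(x) − A) / max(t(x), t0) + A,

where `A` is the per-channel mean of the hazy image over the 0.2% brightest
dark-channel pixels, `ω` (default 0.9) preserves a little haze for realism
and `t0` (default 0.1) bounds the denominator.

The package's core contribution is how the window `Ω` is chosen.  Instead
of one fixed size, a **contrast code image** (CCI) stores per pixel a code
`c ∈ {1..7}` selecting the window size `2c + 1` (3×3 … 15×15).  Codes start
at 7 and a smaller window displaces the incumbent only if its local
standard deviation undercuts the incumbent's by a tolerance `t` per code
step:

    σ_c < σ_best · (1 − t/100)^(c_best − c)

At `t = 5%`, jumping from 15×15 straight to 3×3 therefore requires
`0.95^6 ≈ 73.51%` of the larger window's σ.  Homogeneous regions keep
large windows (stronger prior, darker dark channels); textured regions get
small windows (no halos); and the selection adapts automatically when the
image is rescaled.  The raw transmission map is refined with a fast guided
filter (subsampling ratio `s = 4`, radius `r = 28`, smoothing `ε = 0.45`)
before radiance recovery.

The package also provides the blind evaluation scores used for this kind
of enhancement — the visible-edge **e-score**, the gradient-ratio
**r-score** (both on Canny edges with thresholds 0.2/0.05) and the
**Global Contrast Factor** — plus a deterministic synthetic-scene
generator with known transmission ground truth.

## Worked example

```r
library(darklift)

# a 96x128 synthetic deep-sea scene: dark seafloor, one textured structure,
# lighting that falls off from right to left
sp <- scene_spec(
  seed = 3, height = 96, width = 128, background = 0.3,
  regions = list(
    list(type = "texture", rows = c(20, 60), cols = c(20, 60),
         base = 0.5, amplitude = 0.4, kind = "noise"),
    list(type = "flat", rows = c(70, 90), cols = c(80, 120), intensity = 0.45)
  ),
  t_field = list(type = "ramp", from = 0.3, to = 0.9)
)
scene <- make_scene(sp)
low <- make_lowlight(scene$image, make_t_field(sp), sp$airlight)

res <- enhance(low)   # default parameters: omega 0.9, tolerance 3%, ...
print(res)
#> Contrast-guided enhancement result
#>   image: 96 x 128
#>   airlight: (0.805, 0.840, 0.875)
#>   transmission (refined): [0.123, 0.264]
#>   non-3x3 code share: 6.6%

rep <- metric_report(low, res$enhanced)
cat(sprintf("e-score %.3f | r-score %.3f | GCF %.3f -> %.3f\n",
            rep$e_score, rep$r_score, rep$gcf_before, rep$gcf_after))
#> e-score -0.018 | r-score 4.304 | GCF 1.428 -> 6.729
cat(sprintf("mean intensity %.3f -> %.3f\n", mean(low), mean(res$enhanced)))
#> mean intensity 0.241 -> 0.527
```

The mean intensity more than doubles and the r-score of 4.3 says gradients
at visible edges are on average 4× stronger — the dark half of the scene
has become readable.  The slightly negative e-score reflects that this
particular scene's noise texture was already at full contrast; on real
low-light footage, edge counts typically rise.  `res` also carries every
intermediate (`cci`, `dark_channel`, `transmission_raw`,
`transmission_refined`, `airlight`) for inspection.

## Command line

```sh
Rscript inst/scripts/enhance.R INPUT.png --out OUT.png \
    [--omega F] [--tolerance F] [--t0 F] [--airlight-fraction F] \
    [--gf-radius N] [--gf-eps F] [--gf-subsample N] \
    [--dump-intermediates DIR] [--metrics FILE] [--config FILE]
```

`INPUT` may be a file or a directory of PNG/JPEG/TIFF images.  A config
file (flat `key=value` or JSON) can hold defaults; explicit flags win.

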