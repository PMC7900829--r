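# veindyn

Quantification of superficial vein dynamics from near-infrared (NIR) image
sequences.

Dorsal-hand veins appear dark under ~850 nm reflectance imaging because
venous blood is rich in deoxyhemoglobin. Warming the hand dilates these
veins — which is clinically useful before venepuncture or cannulation — and
the dilation relaxes back over minutes once the heat is removed. `veindyn`
implements the full measurement chain needed to quantify that response from
an NIR video, plus a synthetic-data generator so every stage is testable
end-to-end without patient data:

* **Synthetic scenes** (`scene_spec()`, `render_sequence()`): dark vessels
  with Gaussian absorption cross-sections on a reflective background, a
  dark fiducial mark, per-frame translational jitter, programmable dilation
  tracks, seeded noise — with per-frame ground truth (masks, true
  diameters, injected motion).
* **Stabilization** (`align_sequence()`): exhaustive-search block matching
  (sum of absolute differences) within a high-contrast ROI, integer
  displacements up to a search radius, plus a normalized profile-uniformity
  QC (`profile_uniformity()`).
* **Segmentation** (`build_segnet()`, `train_segnet()`, `predict_mask()`):
  a compact seeded encoder–decoder convolutional network (3×3 convolutions,
  2×2 pooling/upsampling, skip connections, sigmoid output) implemented in
  the package with compiled conv primitives — no external deep-learning
  framework.
* **Calliper** (`measure_region()`, `fwhm()`, `single_line_diameter()`):
  vein diameter as the full width at half maximum (FWHM) of the inverted
  intensity cross-section, sampled perpendicular to a user-drawn polyline
  and averaged over a region,

  `VD = FWHM of (−profile), half-maximum referenced to the local background`.

* **Dynamics** (`percent_dv()`, `fit_decay()`, `correlate_vd_tskin()`,
  `fit_prediction_model()`, `bland_altman()`, `paired_ttest()`): the
  dilation statistic `%DV = max(VD)/VD_base × 100`, negative-exponential
  relaxation `y(t) = c + a·exp(−t/τ)`, the final-diameter regression
  `VD_fin = b0 + b1·T_skin_ini + b2·VD_ini + b3·T_skin_fin` (also exposed
  with its published coefficients via `vd_model_published()`),
  Bland–Altman limits of agreement `bias ± 1.96·sd`, and paired two-tailed
  t-tests.
* **Pipeline** (`run_config()`, `run_pipeline()`): align → segment →
  measure → dynamics with CSV/JSON/PNG outputs and a seed-recording
  manifest. A thin command-line wrapper lives in `inst/cli/veindyn.R`.

All results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods, so they drop straight into dplyr/ggplot2 workflows.

## Worked example

Measure a synthetic dilating vein end to end, then ask the classic
question: by how many percent did it dilate?

```r
library(veindyn)

# a 256x256 scene: one 2.29 mm vessel, a dark fiducial mark, noise sd 2
cl <- cbind(seq(10, 246, length.out = 7),
            128 + 14 * sin(seq(0, pi, length.out = 7)))
sp <- scene_spec(c(256L, 256L), mm_per_px = 0.1,
                 vessels  = list(vessel(cl, diameter_mm = 2.29, depth = 80)),
                 fiducial = fiducial(c(40, 215), radius = 5, level = 15),
                 noise_sigma = 2, seed = 11)

# control frame + 6 post-stimulus frames following the mean dilation
# time course, with integer hand jitter
cfg <- run_config(
  out_dir = "run1", seed = 5,
  synth = list(
    spec     = sp,
    motion   = motion_track(dy = c(0, 4, -3, 2, -5, 1, 3),
                            dx = c(0, -2, 5, -4, 1, 3, -1)),
    dilation = dilation_track(c(1, 1.393, 1.258, 1.127, 1.092, 1.035, 1))
  ),
  t_min = 0:6,
  calliper = list(half_length = 35)
)
res <- run_pipeline(cfg)   # trains the CNN on scene-matched pairs (~3 min)

res$diameters[, c("frame", "t_min", "n_valid", "mean_mm", "sd_mm")]
#> # A tibble: 7 × 5
#>   frame t_min n_valid mean_mm  sd_mm
#>   <int> <dbl>   <int>   <dbl>  <dbl>
#> 1     1     0     120    2.30 0.0180
#> 2     2     1     120    3.20 0.0386
#> 3     3     2     120    2.90 0.0246
#> 4     4     3     120    2.60 0.0325
#> 5     5     4     120    2.51 0.0931
#> 6     6     5     120    2.39 0.0314
#> 7     7     6     120    2.30 0.0158
```

The truth is `2.29 × scale` per frame; every measured mean is within 1% of
it, the stabilizer recovered every injected shift exactly, and the measured
maximum increment (`res$dynamics$vessel1$increment_pct`, 38.8%) sits within
half a percentage point of the programmed 39.3%.

The tabular statistics work standalone. The printed group mean time course
of the low-room-temperature study (baseline 2.29 mm, then 3.19, 2.88,
2.58, 2.50, 2.37 mm) gives:

```r
percent_dv(c(3.19, 2.88, 2.58, 2.5, 2.37), vd_base = 2.29)
#> # A tibble: 1 × 2
#>   percent_dv increment_pct
#>        <dbl>         <dbl>
#> 1       139.          39.3
```

i.e. the vein was maximally 39.3% wider than baseline. And the published
final-diameter regression predicts, for a subject starting at 33.0 °C skin
temperature with a 2.30 mm vein and warmed to 36.0 °C:

```r
predict_vd(vd_model_published(), tskin_ini = 33, vd_ini = 2.30, tskin_fin = 36)
#> # A tibble: 1 × 2
#>   vd_pred_mm model_source
#>        <dbl> <chr>
#> 1       6.80 published
```

(the magnitude of that prediction is a property of the published
coefficients — see the methods vignette for discussion).

## Vignette

`vignettes/vein-dynamics-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, the numerical choices
(baselines, tie-breaks, degenerate inputs), and known limitations.
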