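---
title: "Measuring superficial vein dynamics from NIR image sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring superficial vein dynamics from NIR image sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veindyn)
```

## The measurement problem

Superficial veins of the dorsal hand appear dark under near-infrared (NIR,
~850 nm) reflectance imaging because venous blood is rich in
deoxyhemoglobin while the surrounding skin is highly reflective. Local
warming dilates these veins — clinically useful before venepuncture or
cannulation — and the dilation then relaxes over minutes once the heat
source is removed. Quantifying that response from an NIR video requires
four processing stages, each of which this package implements and tests on
synthetic data with known ground truth:

1. **Stabilization.** Hand micro-motion between frames is estimated by
   exhaustive-search block matching on a high-contrast region (a dark skin
   mark works well) and undone by translating each frame.
2. **Segmentation.** A compact encoder–decoder convolutional network maps
   each frame to a per-pixel vein probability map.
3. **Calliper.** Vein diameter (VD) is defined *operationally* as the full
   width at half maximum (FWHM) of the inverted intensity cross-section,
   sampled perpendicular to a user-drawn polyline and averaged along a
   region.
4. **Dynamics.** Percent dilation, negative-exponential relaxation fits,
   the VD–skin-temperature correlation, a multiple linear-regression model
   for the final diameter, Bland–Altman agreement and paired t-tests.

## The synthetic scene generator

No public NIR vein recordings with ground truth exist, so the package ships
a first-class generator (`scene_spec()`, `render_frame()`,
`render_sequence()`) whose output *defines* the conditions every downstream
stage is tested under.

A vessel is a polyline centerline with a nominal diameter \(D\) (mm) and an
absorption depth \(A\) (gray units). Its rendered cross-section is an
inverted Gaussian,

\[ I(d) = B - A \exp\!\left(-\frac{d^2}{2\sigma^2}\right),
   \qquad \sigma = \frac{D / p}{2\sqrt{2\ln 2}}, \]

where \(d\) is the distance to the centerline, \(B\) the background gray
level and \(p\) the calibration in mm/px. The Gaussian shape matches what
real cross-vein intensity profiles look like, and — crucially — its FWHM in
pixels *equals* \(D/p\), so the nominal diameter is simultaneously the
ground truth for the FWHM calliper. The ground-truth mask is the region
where absorption exceeds half its peak, i.e. the half-maximum region, which
makes mask width and FWHM mutually consistent. A filled dark disk plays the
role of the fiducial skin mark; per-frame translation is applied to the
scene geometry (exact for real-valued offsets); seeded Gaussian pixel noise
is added last.

Calibration is an explicit parameter, default 0.1 mm/px: the acquisition
geometry it emulates only fixes a scale bar, so all px↔mm conversion in
this package is self-defined through `mm_per_px`.

What the generator deliberately does **not** emulate: specular skin
reflections, depth-dependent blur, illumination gradients, non-Gaussian
vessel profiles, or non-translational motion (rotation, perspective).
Passing tests therefore demonstrate correctness of the *computations*, not
robustness to every artifact of real skin imagery.

The cohort generator (`cohort_params()`, `simulate_cohort()`) plays the
same role for the tabular statistics. Each subject draws a baseline skin
temperature and vein diameter, and a final skin temperature; the final
diameter follows the linear generating model

\[ VD_{fin} = b_0 + b_1\,T^{ini}_{skin} + b_2\,VD_{ini} +
   b_3\,T^{fin}_{skin} + \varepsilon, \]

with the published coefficients \((-17.9,\ 0.28,\ 0.93,\ 0.37)\) as
defaults. Post-stimulus time courses relax toward baseline as
\(y(t) = c + a e^{-t/\tau}\) with the amplitude pinned so the series passes
exactly through the generated final value — hence with
\(\sigma_\varepsilon = 0\) ordinary least squares recovers the generating
coefficients to machine precision, which is the package's strongest
self-consistency check.

Defaults were chosen once from the study conditions being emulated:
baseline diameter 2.29 ± 0.45 mm (the low-room-temperature group),
\(\tau_{VD} = 1.6\) min (matching the printed 5-minute mean VD time course
2.29 → 3.19 → 2.88 → 2.58 → 2.50 → 2.37 mm), \(\tau_{T} = 3.5\) min (skin
temperature demonstrably does not return to baseline within 5 min), and a
residual sd of 0.3 mm, consistent with reported ±0.6 mm limits of
agreement (1.96 × 0.3 ≈ 0.59). One caveat is inherited from the published
coefficients themselves: with plausible temperatures (e.g. 33 °C initial,
36 °C final) they predict final diameters far above baseline
(`predict_vd(vd_model_published(), 33, 2.3, 36)` ≈ 6.8 mm). The generator
reproduces this structure faithfully rather than "fixing" it, because the
tests concern recovery of the statistical structure, not physiological
plausibility of the constants.

## Stabilization choices

Block matching uses the sum of absolute differences (SAD) over the whole
ROI block — deterministic, cheap, and standard for this task. The search is
exhaustive over integer displacements within `search_radius` (default
15 px); ties are broken by the smaller displacement norm, then row-major
order, so featureless blocks resolve to (0, 0) and are flagged (and warned)
as degenerate. Frame 1 is always the reference. Only integer displacements
are estimated — the synthetic motion model is translational jitter and the
measurement target (FWHM of a ≥ 10 px wide profile) is insensitive to
sub-pixel residuals; sub-pixel refinement is explicitly out of scope.
Exposed borders after translation are filled with the median gray of the
reference frame, a robust proxy for the skin background.

The quality check mirrors practice: inside a box centred on the fiducial,
each frame's min–max-normalized mean-intensity profile should coincide
across frames once aligned. The `profile_uniformity()` dispersion score
(mean across positions of the across-frame sd) drops from ~0.27 to ~0.005
on a typical jittered synthetic sequence.

## The segmentation network

No deep-learning framework is assumed: the network is implemented in the
package itself, with the convolution/pooling primitives in compiled code
(single-precision im2col + GEMM, fixed accumulation order) and the training
loop in R. The architecture is the smallest encoder–decoder that passes the
held-out Dice target on the synthetic fixture: `depth` stages of 3×3
convolution + ReLU + 2×2 max-pool, a bottleneck convolution, then mirrored
2×2 nearest-neighbour upsampling with skip concatenation (on by default,
configurable off) and 3×3 convolutions, and a final 1×1 convolution with
sigmoid. Defaults: depth 2, base 8 filters (doubling per stage, ~12k
parameters), binary cross-entropy loss, Adam at 5×10⁻³, batch size 2,
20 epochs. Inputs are center-cropped to the 256×256 network size and
mapped to a zero-centred range (`x/255 − 0.5`); the centring matters
because NIR frames are dominated by the bright skin background, and an
uncentred input wastes much of a short training schedule learning the bias.

Every random draw (He-scaled initialization, batch shuffling) flows from
the configuration seed, so a fixed configuration reproduces identical
weights and loss histories on a fixed platform. On the standard fixture —
16 training and 8 held-out 256×256 scenes with one or two curved vessels
(diameters 1.5–3.5 mm, absorption 60–100, noise sd 2) — the network reaches
a mean held-out Dice ≈ 0.95 after the 20-epoch schedule (a few minutes of
CPU time; the fixture sizes were chosen so the whole training run stays at
desk scale).

For measurement, a prediction is rendered back into a dark-vessel image as
`background × (1 − prob)` (`masked_image()`). Because the ground-truth mask
is the half-maximum region, the FWHM of this rendered dip coincides with
the vessel's true diameter on a well-trained network — this is what makes
"measure on the CNN-masked image" (the pipeline default) consistent with
"measure on the raw image".

When the pipeline trains its network on synthetic pairs it samples dilation
scales from 0.9–1.6, slightly wider than the 1.0–1.4 range a study-like
dilation track actually visits, so all measured scales lie in the interior
of the training distribution (boundary scales otherwise show a small
systematic mask-width bias).

## Calliper numerics

`slice_profiles()` places slice centers every `spacing` px (default 2) of
arc length along the polyline, including both endpoints, and samples
`2 × half_length + 1` bilinear-interpolated values along the local
perpendicular at 1-px steps. Tangents are the local segment direction,
averaged at interior vertices.

`fwhm()` inverts the profile and takes the **local background** as
reference: the mean of the outer 10% of samples at each end. This makes the
half-maximum level robust to the global illumination level, at the price of
requiring the profile to reach background — hence the guidance
`half_length ≈ 3×` the expected vessel radius (and that is the pipeline
default's intent; callers measuring wide vessels should widen it). Peaks
are local maxima of the inverted profile; the peak nearest the slice center
wins (the polyline is the user's assertion of where the vein is), ties
going to higher prominence. Crossings are located by linear interpolation
between bracketing samples — no function fitting — which bounds the
discretization error at about 1% for a Gaussian with σ = 2 px and vanishes
for wider vessels. Two conditions yield a *rejection* (a reported reason,
not an exception): peak prominence below `contrast_floor` (default 5 gray
units) and a half-maximum crossing not bracketed inside the profile.
`measure_region()` averages valid slices only and reports the rejection
count; a region whose every slice is rejected is an error naming the
region.

Degenerate and edge cases with defined behaviour: flat profiles are
rejected ("no peak"); a constant series in `fit_decay()` is reported as
degenerate (`a = 0`, undefined R²) rather than an error; all-zero
differences in `paired_ttest()` report p = 1 by convention; a probability
map of exactly 0.5 thresholds to an all-ones mask (the mask is
`prob ≥ threshold`).

## Dynamics choices

* Percent dilation: `%DV = max(series)/base × 100`; the reported increment
  is `%DV − 100`. Scale-invariant by construction. Applied to the printed
  study-A group means (2.29 mm baseline, maximum 3.19 mm) it gives 39.3%.
  Note that the same arithmetic applied to the second study's printed means
  (3.35/3.08) gives 8.77%, slightly below the 9.19% summary value quoted
  alongside them; the package reports what the printed means imply.
* Decay fits use Levenberg–Marquardt (via minpack.lm) on
  \(y = c + a e^{-t/\tau}\) with deterministic initialization
  (\(c_0 = \min y\), \(a_0 = y_1 - c_0\), \(\tau_0 = \mathrm{range}(t)/2\))
  and a bounded set of jittered-τ restarts. The offset \(c\) is essential —
  skin temperature does not decay to 0 °C.
* The prediction model is ordinary least squares of the final diameter on
  (initial skin temperature, initial diameter, final skin temperature),
  exposed both as a refittable `vd_model` and as the fixed published
  coefficients (`vd_model_published()`); every prediction records which
  source was used.
* The paired t-test is two-tailed Student's on the differences, matching
  the before/after design. No multiple-testing correction is applied
  anywhere — none is applied in the emulated analysis either — so users
  comparing many regions or groups should correct externally.
* Bland–Altman limits are `bias ± 1.96 sd` with the sample (n−1) sd; on
  Gaussian differences they cover ≈95% of pairs, which the test suite
  checks empirically on a 10⁴-sample fixture.

## Conventions

Everything is (row, col), 1-based, inclusive — the native R convention —
including polyline vertices in JSON annotation files and ROIs
(`roi(row, col, height, width)`). Millimetre values are always derived
from pixel measurements via an explicit `mm_per_px`; nothing stores mm
redundantly without its calibration. Time is minutes with t = 0 at
"thermal stimulus off"; frames with `t_min ≤ 0` are pre-stimulus, and the
last of them is the control/baseline.

## Problem sizes used by the test suite

The suite renders its fixtures at run time: contract tests use 16–128 px
scenes; the segmentation and end-to-end checks use the standard 256 px
fixture (16 + 8 scenes, depth 2 / base 8 / 20 epochs) and a 7-frame
pipeline run with the study-A mean dilation track, integer jitter up to
5 px and noise sd 2. These sizes were picked as the smallest at which the
measured quantities are stable: diameters ≥ 10 px keep FWHM discretization
error well under 1%, and 16 training scenes are enough for the network to
reach Dice ≈ 0.95 on held-out scenes.

## Known limitations

* Purely translational, integer-pixel stabilization; no rotation, scaling
  or sub-pixel refinement.
* The network is a fixed-topology CPU implementation intended for
  desk-scale training on synthetic or small manual datasets, not a
  general-purpose deep-learning stack; inputs larger than the network size
  are center-cropped (no tiling).
* The calliper assumes one dominant vessel per slice near the polyline;
  crossing vessels resolve by the nearest-to-center rule, which can pick
  the wrong structure if the polyline is drawn carelessly.
* The synthetic generator's realism limits are listed above; conclusions
  about real NIR imagery require validation against manual masks, for
  which a PNG mask loader (`read_mask_png()`) is provided.
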