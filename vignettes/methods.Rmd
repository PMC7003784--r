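---
title: "Pixelwise mapping of facial skin colour change: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixelwise mapping of facial skin colour change: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemap)
```

## The problem

A vehicle-controlled cosmetic study photographs each subject's face at
baseline (T0) and after treatment (T28). The classical analysis averages
the CIELAB colour parameters over a few predefined regions and tests the
per-subject change; this under-estimates effects that are smaller than the
region and misses effects outside it. `facemap` instead registers every
face into a common anatomical frame and runs the paired analysis at every
pixel, so localized colour changes are detected and displayed where they
happen.

This vignette documents the models, the tunable parameters and the design
decisions, in the order the pipeline applies them.

## Colour model

All analysis happens in CIELAB under D65 with the 2° observer — the
standard interpretation of sRGB imagery. The sRGB→XYZ matrix is derived
from the IEC chromaticity primaries with the white column-normalized, so
pure white maps to exactly (L\*, a\*, b\*) = (100, 0, 0); the forward and
inverse conversions round-trip within one 8-bit level over the whole cube.

The colour difference is CIE76, ΔE = √(ΔL\*²+Δa\*²+Δb\*²). This choice is
deliberate: the relevance map's visibility cut-off, ΔE > 1, is the
classical CIE76 just-noticeable-difference convention, and mixing a
CIEDE2000 distance with a CIE76 threshold would misstate visibility.
CIEDE2000 is implemented (`delta_e(..., method = "ciede2000")`, verified
against the standard worked pairs) but is never the default.

The individual typology angle, ITA° = atan2(L\*−50, b\*)·180/π, classifies
skin tone; the two-argument arctangent makes it total (±90° at b\* = 0,
0° at the degenerate origin). The synthetic generator's default base
colour, Lab (50.2, 13, 16), has ITA° ≈ 0.7° — an intermediate skin tone
typical of the population such studies target.

## Chart calibration

Each photograph embeds a 48-patch colour chart. The correction is affine
in sRGB — `reference ≈ M · measured + offset`, least squares over the
patches — the minimal model that absorbs both gain (illumination
intensity/colour) and offset (flare) drift between acquisitions. Patch
*localization* is intentionally out of scope: chart geometry is
device-specific, so measured patch means enter via the chart CSV and the
fit is decoupled from detection. Rank-deficient patch sets (a degenerate
chart) abort with an explicit error. The fit residual is reported as the
mean post-fit ΔE over patches; on synthetic distortions it is numerically
zero and a distorted image is restored within one 8-bit level.

## Registration

Sixty landmark points per image, in a fixed anatomical order, drive the
registration. Landmark *detection* is deliberately pluggable — any
detector (or manual annotation) that emits the JSON landmark format can
feed the pipeline; the package ships none, and all tests supply landmark
files from the generator.

Right facial sides are mirrored about the vertical axis
(`x ← width − 1 − x`) so both sides of a subject occupy one left-side
frame; an index permutation restores anatomical correspondence where the
landmark ordering is side-dependent (the generator stores right-side
landmarks pre-permuted, so the identity suffices there).

The reference shape is the per-landmark arithmetic mean over all images —
faces are position-stabilized at acquisition, so no Procrustes step is
needed or applied. Each image is then warped onto the reference raster
(default: the median input size) with a thin-plate spline fitted from the
reference landmarks to the source landmarks. TPS was chosen over
black-box diffeomorphic schemes because it is deterministic,
landmark-exact (residuals ≤ 10⁻⁶ px), reproduces affine displacements
exactly, and is auditable; the price is that it is not guaranteed
diffeomorphic, so the warp's Jacobian determinant is probed on a 16×16
grid and any non-positive value raises a recorded `folded` warning. A
regularization weight `tps_lambda` (default 0 = exact interpolation)
trades landmark exactness for smoothness if a noisy detector demands it.

Resampling is bilinear with 0-based pixel-centre coordinates; samples
outside the source image are masked out, never extrapolated, and for Lab
images a warped pixel is valid only when all four bilinear neighbours are
valid. Bilinear sampling cannot overshoot the local value range, which
keeps Lab values physical.

## Averaging and the stacks

Per subject, the registered left and mirrored-right images are merged:
averaged where both are valid, the valid one used where only one is — one
facial-side image per subject, matching the study design in which both
sides are pooled (treating sides as independent observations would double
*n* and overstate significance; merging is the conservative default).
Subjects stack in sorted-id order — the pairing contract between time
points — and the stack mask is the conjunction of the per-subject masks,
so statistics are only computed where every subject contributes. The
per-pixel statistic is the plain mean with sample SD (n−1); an optional
trimmed mean (`trim`) is available for outlier-heavy data but is off by
default, the transparent choice.

## The per-pixel paired analysis

For a group with stacks at both time points (identical subject order
enforced), `change_maps()` computes per pixel and channel the mean paired
difference, its sign, the CIE76 ΔE of the three mean differences, and the
two-sided paired Student's t-test p-value on the per-subject differences
(df = n−1). Degenerate pixels are made total without fabricating
significance: all-zero differences give p = 1; constant non-zero
differences (possible on noiseless synthetic data, vanishingly unlikely on
photographs) take the vanishing-variance limit, stored as the smallest
positive double rather than an exact 0, and are counted in the QC
summary.

No multiple-testing correction is applied by default: the method reports
raw per-pixel *P* < 0.05, and the maps are read as descriptive fields
rather than family-wise inferences. Benjamini–Hochberg adjustment over
the masked pixels is one flag away (`fdr = TRUE`) for users who want it;
it can only weaken significance, which a test asserts.

Both map thresholds are strict inequalities — ΔE **>** 1 for visibility,
*P* **<** 0.05 for significance — and boundary cases are tested (a pixel
at exactly ΔE = 1 is not visible).

### Renderings

The relevance rendering maps ΔE linearly from the threshold (darkest
visible grey, 8-bit 64) to the 99th percentile of visible ΔE (white),
overlaid on the average face; the percentile cap keeps a single extreme
pixel from flattening the ramp. Significance renderings blend blue (for
the desired anti-ageing direction: higher L\*, lower a\*, lower b\*) or
red (the opposite) into the average face with weight
min(−log₁₀ p, 4)/4 — the hue and the 0.05 cut are the method's
convention; the intensity encoding is this package's choice, capped so
that p below 10⁻⁴ saturates instead of hiding milder pixels.

## The classical comparator

`roi_change_table()` reproduces the region-of-interest analysis: four
polygons (forehead, upper/middle/lower cheek) fixed **in reference
space** — registration already aligns anatomy, so per-subject template
matching is unnecessary; the shipped rectangles approximate the
conventional placements and are user-replaceable via JSON. Region means
take pixels whose centres fall inside the polygon (even-odd rule),
intersected with the image mask. Both the paired t-test and the exact
Wilcoxon signed-rank test are always reported — the original protocol
alternates between them without stating a rule, so reporting both and
flagging on the t-test is the reproducible resolution.

## The synthetic study generator

`generate_study()` emulates the target study design: two parallel groups
(vehicle/active, default 27 subjects each), two time points 28 days
apart, two facial sides per subject, a 48-patch chart per image. Faces
are schematic — an ellipse with a smooth Lab gradient, darker eye/brow/
mouth features for registration structure, 60 template landmarks — because
the method's correctness is geometric and statistical, not perceptual.
Defaults: 128×128 rasters (a scaled-down stand-in for the 3648×5472
clinical photographs), landmark jitter σ = 1.5 px emulating detector
noise, and independent per-pixel, per-subject Gaussian colour noise
σ = 1 Lab unit per channel, the scale at which per-region changes of a
few tenths of a unit (as such studies report) are plausible; a smoothed
noise option mimics spatially correlated registration residuals. Effects
are circular patches shifting one channel for one cohort, optionally with
between-subject magnitude variability (`effect_sd`).

What the generator does **not** model — pose variation beyond landmark
jitter, specular highlights, hair occlusion, photorealistic texture —
bounds what green tests prove: the pipeline's geometry, calibration and
statistics are correct, not that any particular detector or camera meets
its assumptions.

Determinism is a contract: the same configuration (seed included)
reproduces every file byte-for-byte, and the manifest carries md5
checksums.

## Numerical choices and problem sizes

* TPS kernel U(r) = r² log r evaluated from squared distances (exact 0 at
  r = 0); duplicate landmarks abort with a singular-system error.
* Registered stacks and map matrices serialize as 32-bit float TIFF,
  affinely scaled into [0, 1] with the transform in a JSON sidecar
  (round-trip error ~10⁻⁷ Lab units).
* Test and acceptance problem sizes are scaled to the method, not the
  hardware: type-I calibration uses n = 20/group on ≥10⁴ masked pixels
  (binomial tolerance [0.035, 0.065] at α = 0.05); power checks use
  n = 24 at d/σ ∈ {0.5, 1} against the closed-form noncentral-t power
  within ±3 points; the end-to-end check runs 2 × 12 subjects at
  256×256 and asserts byte-identical reruns.

## Known limitations

* Raw per-pixel p-values are spatially correlated through registration
  and optics; cluster-level or mixed-model inference is out of scope.
* The affine chart correction cannot absorb channel-nonlinear drift
  (e.g. strong white-balance curves); a root-polynomial model would be
  the next step.
* TPS is only diffeomorphic-in-practice; the fold diagnostic reports, but
  does not repair, folded warps.
* ROI polygons fixed in reference space assume the registration is good;
  with a poor landmark detector the classical comparator inherits its
  errors.
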