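---
title: "Methods: segmenting, sizing and weighing olives from conveyor-mat images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting, sizing and weighing olives from conveyor-mat images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivesizer)
```

## The problem

Table-olive grading and oil-yield estimation both need per-fruit size
(major/minor axis length) and mass, but weighing and calipering whole
batches by hand is impractical. olivesizer implements an image-analysis
route: olives are spread without touching on a bright, weakly saturated
mat, photographed from above under fixed lighting, segmented, and measured;
image measurements are then mapped to millimetres and grams by linear
calibration against a reference subset measured with caliper and balance.

## The segmentation model

Olives differ from the mat in two nearly independent ways: they are darker
(low HSV value V) and they are strongly colored (high HSV saturation S).
Shadows cast on the mat are darker too, but shadowing scales all RGB
channels by a common factor, which lowers V while leaving the hexcone
saturation S = (max − min)/max unchanged — so saturation separates shadow
from fruit. The pipeline therefore works on the fused channel

    I_SV = S + (255 − V)

computed on 8-bit rescaled channels (saturating addition; mat pixels map
near 0, fruit pixels near 255). The stages, with defaults:

1. **Preprocess** — bicubic downscale to 40% of the captured resolution,
   then a 5×5 Gaussian (σ = 0.8 px) per channel against salt-and-pepper
   noise. All later radii are interpreted at this working resolution.
2. **Fusion** — RGB → HSV, V inversion, saturating S + V_inv.
3. **Background estimation** — grayscale opening of I_SV with a
   50-px-radius Euclidean disk. The disk is chosen large enough to contain
   any olive, so the opening erases fruit while following the mat's smooth
   brightness folds; subtracting it (floored at 0) yields a high-contrast,
   flattened image.
4. **Binarization** — Otsu's clustering threshold over the 256-bin integer
   histogram (exhaustive maximization of between-class variance; ties break
   to the smallest threshold), applied with a strict `> t` rule.
5. **Cleanup** — binary opening with a 3-px disk removes components too
   small to be fruit; reconstruction-based hole filling (background
   4-connected to the border survives, enclosed background becomes
   foreground) removes the specular-highlight holes inside fruit.

### Numerical conventions

Where the method's published description is silent, the package fixes these
conventions (they are config-stable and covered by tests):

* Channels are rescaled to integers in [0, 255] before fusion; the fusion
  saturates at 255 and background subtraction floors at 0, mirroring 8-bit
  arithmetic. A `wide_range` flag keeps the unclipped 0–510 sum and
  rescales the subtracted image to 0–255 before Otsu instead; it is off by
  default.
* The structuring element is the Euclidean disk {(dr,dc): dr² + dc² ≤ r²}.
* All filters and morphology use symmetric (edge-inclusive) reflect
  padding; bicubic resampling clamps to the edge and renormalizes weights,
  so constant images are preserved exactly.
* The Gaussian kernel is the truncated rotationally symmetric Gaussian
  renormalized to sum 1.
* Hole filling treats the background as 4-connected, the dual of the
  8-connected foreground, so diagonal pixel chains cannot drain a hole.
* `min_contrast` (default 10 gray levels): Otsu's method always proposes a
  split, even on a fruit-free mat whose background-subtracted image is only
  quantization noise and a few levels of fold relief (peak ≈ 5 in the
  synthetic scenes). Requiring the high-contrast image to reach 10 levels —
  roughly twice that floor and more than an order of magnitude below the
  ≈ 200-level contrast of actual fruit — makes fruit-free scenes return an
  empty mask with a warning instead of a noise mask. Single-bin histograms
  are likewise reported as degenerate.

## Per-fruit descriptors

Components are labeled with 8-connectivity, deterministically (labels in
row-major order of first pixels). For each component the package computes
its pixel area, centroid, and the ellipse with the same normalized second
central moments as the pixel set: each pixel is treated as a unit square
(adding 1/12 to the diagonal of the coordinate covariance), and with
eigenvalues λ₁ ≥ λ₂ the full axis lengths are 4√λ — the unique scale for
which a filled continuous ellipse returns its true axis lengths. A single
pixel thus measures 4·√(1/12) ≈ 1.155 px, and digital ellipses with
semi-axes ≥ 10 px recover their axes to within 2%.

Pairing components with reference measurements is by greedy
nearest-centroid matching under a distance gate (default 1.5× the median
minor axis). The published experiment only records that measurements were
"associated to the position" of each fruit; the gate-matched rule is this
package's explicit stand-in, and unmatched entries on either side are
always reported rather than dropped.

## Calibration and error metrics

Axis lengths (px) and pixel areas are mapped to mm and g by ordinary least
squares with an intercept (a through-origin flag exists but is off: the
published scatter fits are affine). Training sets are drawn reproducibly,
optionally stratified by feature quartile (largest-remainder apportionment)
so they represent the size spread; the reference protocol is 50 training
fruits with 150 held out for external validation, which the defaults follow.

Validation quality uses three metrics: RMSE; SE, the RMSE relative to the
mean reference value (%); and |E|, the absolute value of the **sum** of
signed errors relative to the summed reference values (%). Note the order
of operations in |E|: signed errors are summed before the absolute value,
so over- and under-estimation cancel — it measures aggregate bias, not mean
absolute error, and can be 0 while RMSE is large. The per-fruit relative
errors e_i = ŷ_i/y_i are exported so external tools can run mean-comparison
statistics on them; no ANOVA is performed in-package.

Segmentation itself is scored at pixel level against ground-truth masks:
precision TP/(TP+FP), recall TP/(TP+FN), and their harmonic mean F. An
evaluation set is pooled by default (counts summed before the ratios,
weighting images by pixel count); per-image averaging is available. True
negatives are never computed, and undefined scores raise errors instead of
silently reporting 0.

## The synthetic scene generator

No imagery was distributed with the original study, so the package ships a
seeded generator emulating the acquisition conditions, and all end-to-end
claims are made against it:

* bright near-achromatic mat (level 232, slight warm tint) with smooth
  brightness folds — three random sinusoids with wavelengths of 1–2× the
  image's short side, so fold half-wavelengths exceed the background
  structuring disk at working resolution, which is what makes
  opening-based background estimation applicable at all;
* fruits as filled rotated ellipses from two color families (dark purple
  and green-brown, per-fruit jitter), axes drawn from 14–24 mm (major) and
  10–18 mm (minor) at 0.25 mm/px — spanning small and large table-olive
  cultivars;
* cast shadows: offset ellipses where all channels are scaled by
  1 − shadow_strength (default 0.25), reproducing the physically relevant
  property that shadows lower value but preserve saturation;
* per-fruit specular highlights: small bright near-achromatic blobs that
  create exactly the interior holes the reconstruction step must fill;
* Gaussian pixel noise (σ = 2) and clipping to 8 bits;
* mass generated as affine in the projected ellipse area,
  mass = 0.011 g/mm² · (π/4 · major · minor) + 0.2 g + N(0, 0.08 g) —
  about 1.2–3.3 g per fruit, realistic for table olives. A `volume_law`
  flag instead makes mass proportional to major·minor² to probe how far
  the area-linear calibration degrades when the true law is volumetric.

Placement is rejection-sampled under a minimum center separation (default
130 px, and never closer than the sum of semi-major axes + 6 px), with a
loud failure after 10,000 attempts. Everything is a pure function of the
seed; datasets regenerate bit-identically from their manifest.

What the generator does **not** emulate: touching fruits (outside the
method's stated operating range), perspective or lens distortion, JPEG
artifacts, specular reflections on the mat, non-elliptical fruit outlines,
and intra-fruit color gradients. Passing the synthetic suite therefore
demonstrates the algorithm's internal correctness and its behavior under
the stated scene model, not performance on any particular camera setup —
real deployments still need their own calibration set, which is exactly
what the pipeline's training stage is for.

## Reference problem sizes

The shipped test-suite and acceptance runs use 720×960 px scenes (288×384
at working resolution), 20 scenes of 10 fruits for segmentation scoring,
and 10 scenes of 20 fruits (200 total, split 50/150) for calibration —
sizes chosen so a complete run takes a few minutes on one core while the
validation-set size matches the reference protocol. On this suite the
pooled F-score is ≈ 0.98, the fruit count is exact in every scene, axis
RMSE ≈ 0.2 mm and mass RMSE ≈ 0.1 g (SE ≈ 1–4%, |E| < 1%); rerun
`scripts/acceptance.R` to reproduce the exact numbers for any seed.

## Known limitations

* Touching or overlapping fruits merge into one component; the method
  requires physical separation (e.g. a cleaved conveyor).
* The linear mass law is a projection-area approximation; for strongly
  prolate cultivars a volumetric law fits better (see `volume_law`).
* The Otsu threshold is global; strong vignetting or lighting gradients
  wider than the background disk are not corrected.
* Calibrations are camera- and height-specific: slopes absorb mm/px scale,
  so any change of optics requires retraining.
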