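---
title: "Normal-line corneal pachymetry and keratoconus staging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-line corneal pachymetry and keratoconus staging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcpachy)
```

## Background

Keratoconus (KC) is a progressive corneal ectasia: the cornea thins focally,
steepens into a cone, and in late disease may scar. Anterior-segment OCT
(AS-OCT) B-scans resolve the epithelium and stroma well enough that the
thickness of the whole cornea and of the epithelial layer alone can be
profiled across the central cornea, and those profiles carry staging
information that curvature-based grading does not use directly.

`kcpachy` implements that profiling pipeline end to end on synthetic
corneal phantoms with analytically known geometry:

1. a **phantom generator** producing per-scan cross-sections, label masks,
   speckled grayscale renders, and exact ground-truth thickness;
2. **boundary extraction** from label masks (exact path) or grayscale
   images (classical gradient path);
3. **normal-line pachymetry**: 40 samples every 0.15 mm over a 6 mm region
   of interest (ROI), thickness measured along the local inward normal of
   the anterior surface;
4. **zone statistics**: 20 zones per profile, group means with 95% CIs,
   one-way ANOVA, Welch t-tests, OLS thickness-vs-stage trends;
5. **stage discrimination**: four thickness ectasia indices per eye and a
   two-class Fisher discriminant of each KC stage against normal, with
   ROC/AUC;
6. **segmentation metrics**: Dice, IoU, sensitivity, specificity, and an
   indirect thickness-error metric.

Stage labels (normal, mild, moderate, severe, scarring) are cohort inputs
throughout; the package never grades an eye from curvature.

## Coordinate and grid conventions

The default scan grid is 2648 x 640 pixels covering 8 mm x 1.933 mm, so one
pixel is ~3 um in both directions. Pixel indices are 0-based with centers on
integers; `x` runs laterally, `y` increases into the tissue. Boundaries in
the mask path live on *pixel edges* (half-integer rows), so a band of `n`
pixels measures exactly `n` times the axial pitch — this keeps thickness
measurements consistent with pixel counting.

## The measurement model

**Reference point.** Scans are pupil-fixated, so the pupil center is taken
to lie at the central image column; the reference point is the
anterior-surface point there. How a pupil center would be detected on a
free-standing B-scan is out of scope.

**Sampling.** The ROI spans 3 mm of arc on each side of the reference
point. It is divided into 40 contiguous 0.15 mm bins; the sample points are
the bin centers, -2.925 ... +2.925 mm. This fencepost choice yields exactly
40 symmetric points and puts the center of zone 9 at -0.45 mm — the
slightly temporal/inferior position where keratoconic corneas are
clinically thinnest. Positions are measured as *arc length along the
anterior surface* rather than chord distance; over +/-3 mm of a ~7.8 mm
radius surface the two differ by only a few percent at the ROI edge, but
the arc convention matches "every 0.15 mm along the surface" and is fixed
here so results are reproducible.

**Normals.** The local surface direction at a sample point is estimated by
a quadratic fit of `y(x)` over a +/-300 um window (at least 5 trace
points). The window is wide enough to average pixel-level jitter (normals
off a 1-pixel-jittered circle stay within 1 degree) and short enough that
corneal curvature is locally quadratic to well below measurement noise.

**Thickness.** From a sample point the measurement marches along the
inward unit normal in 0.5 um steps until the ray first crosses the target
trace (epithelium-stroma interface for epithelial thickness, posterior
surface for corneal thickness), then refines the crossing by bisection to
better than 0.1 um. The first crossing is used if a ray could cross twice;
marching gives up at 2000 um, which no physiological cornea approaches.
For concentric-arc geometry this normal-line distance equals the
nearest-point distance, and the test suite cross-checks the marching result
against a brute-force nearest-distance search.

**Mirroring.** Horizontal scans of right eyes view the cornea
mirror-imaged. Before any between-eye statistics, right-eye horizontal
profiles are mirrored onto the left-eye frame (positions negated —
equivalently the 40 values reversed on the fixed symmetric grid), so that
negative positions are always temporal. Vertical profiles use negative =
inferior in both eyes and are never mirrored.

## The phantom cohort

Each scan is generated independently as a 1-D cross-section:

- the **anterior surface** is a circular arc (default radius 7800 um, the
  typical human anterior cornea), apex 60 um below the image top;
- **corneal thickness** along the arc is
  `T(s) = peripheral - (peripheral - apex) * exp(-(s - s0)^2 / (2 sigma^2))`,
  a Gaussian cone of width `sigma` centered `s0` ~ -0.45 mm
  (temporal/inferior) of the scan center; **epithelial thickness** `E(s)`
  is analogous;
- the interface and posterior curves are constructed by stepping `E(s)` and
  `T(s)` along the inward anterior normal. Because the deeper boundaries
  are *defined* by normal offset, normal-line measurement recovers `T` and
  `E` exactly: the phantom is its own oracle, and any pipeline error is
  attributable to discretization and extraction.

Stage-dependent defaults (`stage_defaults()`): cone-apex corneal thickness
504.5 / 496.0 / 475.7 / 455.3 / 376.1 um and apex epithelial thickness
48.9 / 48.2 / 43.7 / 40.3 / 46.9 um for normal through scarring —
representative central values for staged keratoconus cohorts reported in
the clinical literature — with between-eye spreads (34-55 um corneal)
chosen so that simulated 95% confidence intervals at the default group
sizes (118 / 134 / 239 / 153 / 71 eyes) have clinically realistic widths.
The cone narrows with severity (`sigma` 1.4 mm down to 0.8 mm), sharpening
the focal thinning.

Peripheral thickness tracks the eye's own apex with a stage-independent
mean gap (~115 um corneal, so the normal-stage peripheral default is
620 um) plus its own between-eye variation (40 um s.d. corneal, 2.5 um
epithelial). Two structural choices matter here and were made on realism
grounds:

- *Whole-cornea thinning.* Tying the periphery to the apex rather than
  fixing it at 620 um for every stage makes advanced KC corneas thinner
  everywhere, not only at the cone — without it, peripheral zones would
  show flat or inverted thickness-vs-stage trends, contrary to the
  clinical picture.
- *Epithelial undulation.* Every eye receives a smooth, seeded, zero-mean
  epithelial fluctuation (~0.5 mm correlation length; amplitude ~1.5 um
  normally, ~6 um with scarring, added to a thicker epithelial baseline in
  the scarring stage). Real epithelial profiles are never perfectly
  smooth; without this, the epithelial max/min ectasia index becomes an
  unrealistically noise-free stage marker and every stage separates from
  normal almost perfectly, which no clinical ROC shows.

Horizontal and vertical scans of one eye are generated independently with
their own cone offsets: the scans are treated as 1-D slices and no 3-D
cornea is modeled. Right-eye horizontal scans place the cone on the
mirrored side, so that mirroring during analysis restores the common
orientation. Label masks classify each pixel center as background,
epithelium or stroma; grayscale renders add per-class mean intensities,
multiplicative gamma speckle (contrast 0.25 by default) and, for scarring,
a hyperintense stromal patch near the cone.

**What the phantoms do not emulate:** optical refraction and scan-geometry
distortion, axial point-spread and shadowing artifacts, 3-D cone shape and
between-meridian correlation, hydrops/Descemet-rupture morphology, and the
label noise of human graders. Passing tests on phantoms therefore
demonstrate the *measurement and statistics machinery* — not clinical
segmentation performance, which would require real annotated scans and a
trained segmentation model. The boundary-extraction contract
(`boundary_set`) is exactly what such a model would produce, so a learned
extractor can be slotted in without touching the rest of the pipeline.

## Numerical choices

- **Mask-path smoothing.** Edge tracing quantizes boundaries to
  half-integer rows; near the apex (where the surface is locally flat) the
  resulting staircase has long treads and the raw traces can carry
  ~0.5-pixel systematic offsets that propagate to ~5 um thickness errors.
  `trace_from_mask` therefore smooths each trace with an 11-column
  (~33 um) moving average by default. The curvature bias of that window on
  a 7.8 mm-radius surface is below 0.05 um — two orders of magnitude under
  the quantization it removes. `smooth_window = 1` restores the raw edge
  convention.
- **Image path.** The gradient extractor smooths axially with a
  triangular kernel (a boxcar applied twice, default 7), averages 5
  columns laterally against speckle, places the anterior/posterior at the
  first/last strong gradient peak (>= half the column's peak magnitude),
  the interface at the strongest internal dark-to-bright transition,
  refines peaks parabolically to sub-pixel position, and median-filters
  across columns. Failed columns are interpolated; extraction errors out
  if more than half fail (e.g. a blank image).
- **Gap handling.** Interior no-tissue columns are interpolated from
  neighbors; leading/trailing gaps truncate the trace. Ordering violations
  (stroma above epithelium) are hard errors, never repaired.
- **Statistics.** Welch (unequal-variance) t-tests are used for pairwise
  comparisons — group spreads differ strongly across stages, the scarring
  group most of all. CIs are t-based. Stages enter the trend regression as
  equally spaced ordinals 0-4 including scarring. Raw p-values are
  reported; no multiple-testing correction is applied.
- **LDA.** Two-class Fisher discriminant on the four ectasia indices:
  weights proportional to the pooled-covariance inverse times the mean
  difference, offset centering the score at the midpoint of projected
  class means. If the 4x4 pooled covariance is near-singular (the indices
  are correlated ratios), a ridge of `1e-6 * trace/4` is added. ROC is
  evaluated in-sample (no cross-validation), and ties receive the
  half-credit Mann-Whitney convention, making the trapezoidal AUC equal to
  the concordance probability.
- **Ectasia indices** are computed over the 40 ROI samples, not the full
  scan width; the periphery beyond the ROI is not measured.

## Problem sizes

The test suite and the acceptance script use: the full default cohort
(715 eyes, 1430 scans) measured from exact column-sampled boundary traces
(~2 minutes); 50 rasterized phantoms spanning all stages for the mask-path
oracle bound (max |measured - analytic| <= 4 um, about one pixel); 2000
replicates for the ANOVA type-I error and CI coverage checks; and small
constructed fixtures for every closed-form example. Rasterizing all 1430
scans at full resolution would add nothing: mask-path consistency is a
per-scan property already covered by the 50-phantom sweep.

## Known limitations

- The pupil center is assumed at the scan center; decentered acquisitions
  would bias the ROI placement.
- Boundaries are single-valued in `x` (columns, not rays) — valid for the
  central 6 mm at this field of view, not for limbus-to-limbus scans.
- Eyes are treated as independent units; no patient-level random effects.
- The image-path extractor is a classical stand-in tuned for the phantom
  renders; on clinical scans a trained segmentation model should provide
  the `boundary_set`.
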