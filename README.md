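# kcpachy

Corneal thickness profiling and keratoconus staging from anterior-segment
OCT cross-sections, exercised end to end on synthetic corneal phantoms with
analytically known geometry.

## The problem

Keratoconus (KC) thins the cornea focally — slightly temporal and inferior
of the pupil center — before it becomes clinically obvious from curvature.
AS-OCT B-scans resolve the anterior surface, the epithelium–stroma
interface and the posterior surface well enough to profile both corneal and
epithelial thickness across the central 6 mm. This package implements that
measurement and the downstream staging statistics:

- **Normal-line pachymetry.** With the pupil center as reference, 40 sample
  points are placed every 0.15 mm of arc over a 6 mm region of interest.
  At each point the thickness is the distance from the anterior surface
  along its inward normal to the epithelium–stroma interface (epithelial
  thickness *E*) or the posterior surface (corneal thickness *T*).
- **Zone statistics.** Each 40-point profile is divided into 20 zones
  (zone *j* averages samples 2*j*−1, 2*j*). Per zone: group means with
  95% t-CIs, one-way ANOVA over the five stage groups, Welch two-sample
  t-tests, and the OLS trend of thickness on stage ordinal (0 = normal …
  4 = scarring).
- **Ectasia indices and screening.** Per eye, four indices
  EEI_H, EEI_V, CEI_H, CEI_V = max/min thickness over the profile
  (epithelium/cornea × horizontal/vertical meridian). A two-class Fisher
  LDA — score = w·f + b with w ∝ Σ⁻¹(μ_stage − μ_normal) — separates each
  KC stage from normal, evaluated with ROC/AUC.
- **Segmentation metrics.** Dice, IoU, sensitivity, specificity and the
  mean absolute thickness difference (T_error) between candidate and
  reference segmentations.

The clinical dataset behind such a study is never public, so the package
ships a first-class synthetic cohort generator: a circular anterior surface
with a Gaussian-cone thickness profile per stage, whose deeper boundaries
are built by stepping along the anterior normal — making the phantom an
exact oracle for the measurement. See the methods vignette
(`vignettes/corneal-pachymetry.Rmd`) for the model, parameters and design
choices.

## Worked example

```r
library(kcpachy)

spec  <- make_phantom_spec("severe", "OS", "H", seed = 7)
spec
#> <phantom_spec> severe OS/H seed=7 | CT 568.5->656.2 um, ET 31.8->42.5 um,
#>                cone 0.84 mm @ -0.54 mm

truth <- boundaries_from_spec(spec)
mask  <- rasterize_masks(truth)      # 2648 x 640 three-class label mask
bset  <- trace_from_mask(mask)       # sub-pixel boundary traces
prof  <- measure_profile(bset)       # 40-point profiles, both tissues
prof$cornea
#> <thickness_profile> cornea OS/H (?): 568.6-656.5 um, min 568.6 @ -0.525 mm

pos <- sample_positions()
max(abs(prof$cornea$values - analytic_thickness(truth, pos)))
#> 1.51   # um; about half an image pixel (3.02 um)

max(prof$cornea$values) / min(prof$cornea$values)   # corneal ectasia index
#> 1.155
```

The measured profile finds the thinnest point at −0.525 mm, within one
sample spacing of the generated cone center (−0.54 mm), and recovers the
analytic thickness to well under one pixel.

## Cohort analysis

The `analysis/` scripts run the full workflow on the default cohort
(118 / 134 / 239 / 153 / 71 eyes for normal / mild / moderate / severe /
scarring, one horizontal and one vertical scan each):

```sh
Rscript analysis/01_simulate_cohort.R        # cohort specs table
Rscript analysis/02_measure_profiles.R       # 1430 scans -> profiles.csv
Rscript analysis/03_zone_statistics.R        # zone CIs, ANOVA, trends, t-tests
Rscript analysis/04_stage_screening.R        # ectasia indices, LDA, ROC/AUC
Rscript analysis/05_segmentation_evaluation.R  # Dice/IoU/T_error reports
```

Outputs land in `results/`. On this cohort: corneal-thickness ANOVA is
significant (p < 0.05) in all 20 zones of both meridians, every zone's
thickness-vs-stage slope is negative, the thinnest zone is zone 9
(~0.45 mm temporal/inferior), and the stage-vs-normal AUCs increase with
severity (mild 0.62, moderate 0.93, severe 0.99, scarring 1.00 at the
default seed).

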