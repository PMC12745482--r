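---
title: "Methods: QCT bone densitometry and method agreement in tibiaqct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QCT bone densitometry and method agreement in tibiaqct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tibiaqct` implements, as one tested pipeline, the comparison of two CT-based
protocols for measuring tibial bone mineral density (BMD) in laying hens:

* **M1** — quadrant-based cortical ROI analysis: four circular regions of
  interest, one per anatomical quadrant, placed in homogeneous cortical bone
  of maximal density;
* **M2** — whole-bone analysis: seeded region growing within a density
  window over the entire mineralized cross-section.

Around the two methods sit the hydroxyapatite phantom calibration that maps
Hounsfield units (HU) to mgHA/cm³, the agreement-statistics suite (Pearson,
Bland–Altman, Lin's concordance, Deming regression, CV), and a regression
screen of bone/eggshell traits against per-method BMD. Because no CT data
accompany the study design this package targets, a synthetic-CT generator
with exact ground truth is a first-class module: every downstream stage is
validated against oracles on data whose true density is known by
construction.

# Calibration model

The scanner reports HU; the in-field phantom carries cylinders of known
hydroxyapatite concentration (0, 100 and 200 mgHA/cm³). `read_phantom()`
averages HU over the central 70% radius of each cylinder across all
phantom-bearing slices — the central-fraction rule keeps partial-volume
voxels at the cylinder wall out of the reference, and the exact fraction is a
configuration choice, not a measured constant.

The default calibration is the two-point form

$$\mathrm{BMD} = \frac{200 \cdot HU_t}{HU_b - HU_w},$$

with $HU_b$ and $HU_w$ the 200 and 0 mgHA/cm³ readings. We implement this
equation **verbatim**: note it does not subtract $HU_w$ from the numerator,
so when $HU_w \neq 0$ the line is *not* the interpolation through the water
point. Both behaviours matter in practice, so the interpolating variant
$200 (HU_t - HU_w)/(HU_b - HU_w)$ is available behind
`water_correct = TRUE`, and a least-squares fit over all three cylinders
behind `mode = "least_squares"`; neither is ever silently substituted for
the default. With the generator's default scanner model (HU numerically
equal to density, zero offset) the verbatim two-point form is exactly
invertible, which is what the round-trip tests exploit; with a non-zero
scanner offset only the water-corrected variant recovers ground truth
exactly, and the tests cover that case too.

# Method M1: quadrant ROIs

1. **Bone mask.** The slice is thresholded to the density window
   (200–2000), the phantom region is masked out, and the largest
   8-connected component is kept.
2. **Quadrants.** Orthogonal axes through the unweighted centroid of the
   mask split it into four 90° sectors. The sector boundaries lie on the
   image diagonals, so each sector is centered on a cardinal direction
   (up = anterior, down = posterior, left = medial, right = lateral by
   default). The slice statistic — the mean of four ROI means — is invariant
   to this labelling convention; the diagonal choice simply makes each
   quadrant face its anatomical direction. A pixel exactly on a diagonal is
   assigned to the counter-clockwise sector; the centroid pixel itself
   (angle undefined) goes to anterior. These tie rules make the partition a
   deterministic exact cover, which the tests audit pixel by pixel.
3. **ROI search.** Within each quadrant, every pixel whose disk (default
   radius 2 px ≈ 0.5 mm at 0.25 mm pixels) fits entirely inside the
   quadrant's bone mask is a candidate center. The ROI maximizes mean BMD
   subject to a homogeneity constraint, SD ≤ 0.15 × mean (population SD);
   if no candidate satisfies it, the unconstrained maximum is taken. Ties
   break to the smallest (row, col). "Homogeneous areas with the highest
   radiodensity" is a qualitative instruction; the 0.15 relative-SD
   operationalization and the 2 px radius are configuration defaults chosen
   to be small relative to cortical thickness (~7 px in the default
   geometry), and both are exposed in `pipeline_config()`.
4. **Replicates.** An operator re-placing ROIs never lands on identical
   pixels. We model replicates as re-runs with the candidate grid origin
   jittered by a sub-pixel offset (uniform in ±0.35 px, seeded). When a
   jittered disk covers fewer pixels than the 12-pixel floor it is expanded
   in 0.1 px steps (at most +1 px). If a quadrant cannot fit the disk at
   all, the radius shrinks 1 px at a time to a configured minimum before
   the slice is recorded as failed.

The max-selection step is the structural source of M1's positive bias: on
any slice whose density varies azimuthally or radially, the maximum over
admissible ROI means is at least the whole-mask mean. The test suite checks
this inequality slice by slice, and the cohort-level consequence (per-bone
M1 ≥ M2, negative M2 − M1 bias) across 20 independently seeded cohorts.

# Method M2: seeded region growing

The whole-bone method grows an 8-connected region (2-D, in-plane — matching
a "2D grow region" tool; 3-D growth is deliberately not used) from a seed
pixel through all pixels within the density window, then summarizes the mask:
mean, population SD, min, max, pixel count, area and contributed volume
(area × slice thickness). The window (200–2000) is interpreted on the
calibrated BMD map by default; `threshold_space = "hu"` applies the same
numbers to raw HU instead, since the two spaces coincide only for an
identity-like calibration. Because the conversion is affine with positive
slope, mask membership and ROI rankings are unaffected by which space is
used when the calibration is the default identity.

Seed choice is unspecified in the protocols this package models, so it is
made deterministic: replicate *r* seeds at the *r*-th highest-density
in-range pixel at least 3 px (Euclidean) from earlier seeds, ties
lexicographic. Any two seeds inside the same thresholded component grow the
identical mask, so M2's replicate CV is structurally ~0 — the replicate
mechanism exists to detect seeds landing in different components, not to
inject noise.

The phantom region is masked out before seeding and growing, so the region
can never leak into the 200 mgHA/cm³ cylinder even if a bridge of in-range
noise pixels existed.

# Aggregation and precision

Measurements are taken at three standardized diaphyseal levels — 25%
(proximal), 50% (medial) and 75% (distal) of the slice count from the
proximal end, rounded to the nearest slice with exact halves going to the
*lower* index, 1-based. Aggregation strictly follows replicates → region →
whole bone: the region value is the mean of its three replicates, the
whole-bone value the unweighted mean of the three region values — never a
pooled grand mean of raw records (the distinction matters whenever a cell
loses a replicate). Within-method precision is the CV across the three
replicates of each (bone, region) cell, averaged per method; the default
cohort keeps it far below the 5% benchmark.

# Agreement statistics

All statistics operate on the 48 paired per-bone whole-bone values
(x = M1, y = M2):

* **Pearson r** with the usual t-based p-value (n − 2 df).
* **Lin's CCC**, computed with population (divisor n) moments:
  $\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, decomposed as
  precision × accuracy, $\rho_c = r \cdot C_b$. The CI uses the Fisher
  z-transform with Lin's asymptotic standard error. The identity
  $\rho_c = r C_b$ and $|\rho_c| \le |r|$ are asserted to 1e-12.
* **Bland–Altman** on d = M2 − M1 (that bias direction is fixed throughout):
  mean bias, limits of agreement bias ± 1.96 SD(d) (sample SD), and the
  proportional-bias OLS slope of d on the pair means, flagged as degenerate
  when the differences are constant.
* **Deming regression** with error-variance ratio λ (error_y/error_x).
  λ is not identifiable from the paired values themselves and defaults to 1
  (orthogonal regression); it is exposed in the configuration. CIs are
  leave-one-out jackknife with t quantiles on n − 2 df. The closed-form
  slope is verified in the tests against a numerical minimizer of the
  profiled Deming loss, and the scale/λ→∞/swap invariances are checked
  numerically.
* **Divisor conventions:** population moments (n) inside the CCC formula
  and within-mask SDs (the mask is the entire population of selected
  pixels); sample moments (n − 1) for descriptive SD/CV and the
  Bland–Altman SD. These follow each statistic's conventional definition.

A Shapiro–Wilk screen is available as an optional pre-check
(`check_normality = TRUE`); it warns and never gates computation.

# Trait model and regression screen

Nine traits are modelled: bone weight (g), length (mm), volume (cm³),
mineral matter (g and %), Seedor index (mg/mm, weight/length), eggshell
weight (g), thickness (mm) and breaking strength (N). The generator draws
each as a linear function of the bone's true mean BMD plus Gaussian noise,
with slopes positive for bone weight/volume, negative for the eggshell
traits and mineral mass, and zero for length, mineral % and Seedor index —
the sign structure of the biological trade-off in which hens with higher
skeletal mineralization export less calcium into shell. Residual SDs are set
from target population R² values through the closed form
$s = |b|\sqrt{\mathrm{var}(D)(1-R^2)/R^2}$ (`noise_sd_for_target_r2()`),
anchored at realistic trait means for a 48-week Dekalb White hen
(≈8 g tibia, 110 mm, 7 cm³, 5.8 g shell, 0.37 mm, 38 N).

The screen regresses each trait on per-method BMD, by default normalized by
bone volume first. One consequence of normalizing by a trait that is itself
in the screen deserves note: the association between bone volume and
BMD/volume involves the regressor's own denominator and is positive only
when the BMD–volume correlation is high. The default volume R² target
(0.85 against raw true BMD) is set in that regime, so the screen's expected
sign pattern is stable at n = 48; `volume_normalize = FALSE` re-runs the
screen on raw BMD. Results are reported as signed R² — `sign(slope) · R²` —
a reporting convention that restores the direction information R² discards
(a genuinely negative coefficient of determination does not exist). Both R²
and signed R² are emitted. No multiple-testing correction is applied to the
primary screen (per-trait α = 0.05); a Benjamini–Hochberg column is included
as supplementary output only.

# The synthetic generator

Each bone is an elliptic-annulus cortical shell around a medullary interior,
extruded along 110 slices (1 mm thickness and interval) on a 128 × 128 grid
of 0.25 mm pixels, with the phantom ventral to the bone in every slice.

What it emulates, and the defaults (all configurable in `cohort_spec()`):

* **Cortical density** mean 1000 mgHA/cm³, between-bone SD 160 — producing
  per-method cohort means and SDs in the published range for laying-hen
  tibia (roughly 400–800 mgHA/cm³ whole-bone, with quadrant-style readings
  several hundred units higher).
* **Azimuthal modulation** (relative amplitude 0.12 ± 0.04 between bones,
  random phase) and a **radial gradient** (+60 mgHA/cm³ periosteal minus
  mid-cortex): the heterogeneity M1's max-density search exploits; without
  it the two methods would trivially agree.
* **Medullary bone** at mean 300 ± 40 mgHA/cm³ inside an endosteal boundary
  at 0.58 ± 0.05 of the outer ellipse. Quantitative medullary extent at 48
  weeks is not well characterized; these are plausible placeholders exposed
  as configuration, chosen once.
* **Axial profile** making the midshaft densest (multipliers 0.972 / 1.028 /
  1.000 at the proximal / medial / distal levels), reproducing the regional
  ordering medial > distal > proximal with a ~5% proximal-to-medial spread.
* **Scanner model**: HU = 1 · density + 0 on bone and phantom voxels, soft
  tissue at 40 HU, air at −1000 HU; Gaussian HU noise (SD 30) and a
  separable Gaussian partial-volume blur (σ = 0.5 px). The affine forward
  model is what makes calibration exactly invertible in the noise-free
  limit — the anchor for the 1e-6 round-trip tests.

What it does **not** emulate: X-ray projection and reconstruction physics
(no sinograms, beam hardening, reconstruction kernels or streak artifacts),
anatomically exact tibial geometry, cortical porosity, or operator
variability beyond the seeded jitter. Passing the synthetic validation
therefore demonstrates that the *algorithms* are correct and that the
pipeline reproduces the structural mechanism of the M1–M2 bias; it does not
certify accuracy on any particular scanner's images.

# Numerical conventions and degenerate inputs

* Indices are 1-based, axis order (slice, row, column), slice 1 proximal,
  "ventral" = larger row.
* All tie-breaks are lexicographic smallest (row, col); component labelling
  discovers components in row-major order. These choices make every stage
  bit-reproducible under a fixed seed.
* Degenerate inputs fail loudly and specifically: empty masks, seeds outside
  the density window, phantom cylinders outside the field of view,
  HUb ≤ HUw, identical cylinder readings, zero variance in correlation or
  regression inputs, non-positive lengths/volumes. Per-slice measurement
  failures are logged and excluded with counts in the run manifest; a run
  aborts only if an entire method yields no records.
* Cohorts of fewer than 3 bones skip the agreement report and trait screen
  (their statistics are undefined below that) while still producing
  measurements and summaries.

# Problem sizes used in validation

The validation suite runs the full study-scale configuration once — 48
bones at 128 × 128 × 110, 432 measurements per method — and reuses that run
across checks. Unit and property tests use a compact 96 × 96 × 40 format
that preserves all geometric relations at about a third of the per-bone
cost; the region-growing battery covers 200 random 64 × 64 slices against a
scalar flood-fill oracle; trait-parameter recovery uses simulated cohorts of
n = 10,000. The acceptance script regenerates the 48-bone cohort from
scratch and reports the mean within-method replicate CV.

# Known limitations

* DICOM I/O is not provided; volumes and masks are read/written as NIfTI.
* M2's replicate mechanism is structurally degenerate (identical masks from
  seeds in one component), so its CV understates what an interactive tool
  with operator-chosen windows would show.
* The Deming λ and the CCC/Deming CI constructions are conventional choices
  (λ = 1, Fisher-z + Lin SE, jackknife); alternatives would change CIs but
  not point estimates.
* The generator's trait model is linear with independent Gaussian noise;
  real trait–BMD relations are noisier and partially nonlinear, so the
  screen's power on real cohorts will be lower than on synthetic ones.
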