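---
title: "Methods: trunk muscle-fat% and supine kyphosis analysis on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trunk muscle-fat% and supine kyphosis analysis on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Thoracic kyphosis is conventionally quantified by the Cobb angle — the
angle between a line parallel to the superior endplate of T1 and one
parallel to the inferior endplate of T12/L1 on a sagittal view. Manual Cobb
measurement on CT is reliable but reader-intensive. Intramuscular fatty
infiltration of the trunk muscles, measurable automatically from the same
scans, is a candidate surrogate biomarker: muscle-fat% is defined as the
percentage of voxels within a segmented muscle whose attenuation lies
below −20 HU. This package implements the quantitative core of that
analysis — fat quantification, Cobb geometry, multi-rater reliability,
confounder handling and the correlation study — together with a synthetic
CT phantom and cohort generator so every stage is testable against known
ground truth without any imaging download.

## Muscle-fat% and muscle volume

For a muscle mask $M$ on an HU volume,
$$\text{fat\%} = 100 \cdot \frac{|\{v \in M : \mathrm{HU}(v) < -20\}|}{|M|},
\qquad \text{volume} = |M| \cdot \frac{s_z s_y s_x}{1000}\ \text{mL}.$$

Numerical choices:

* **Strict inequality.** "Below −20 HU" is read literally: a voxel at
  exactly −20 counts as muscle. The threshold and comparison are
  configurable in `fat_quant_config()`.
* **Bilateral pooling.** One value is reported per bilateral muscle group
  by pooling left and right voxels *before* dividing. This equals the
  ratio over the union mask and is *not* the mean of side percentages
  (the two differ whenever sides have unequal volume); the pooled-merge
  identity is asserted in the tests.
* **Raw HU, native grid.** Fat% is always computed on raw HU on the
  native grid. The model-preprocessing transform clips at −95 HU, which
  would censor fat attenuation entirely; an integration test asserts
  fat% is unaffected by preprocessing a separate copy. Whether the
  original analysis quantified before or after resampling is not
  documented; both paths exist here and native is the default.
* **Empty masks are absent, not 0%.** 0% (all muscle) and "no voxels"
  are different statements; `quantify_all()` flags absent groups and
  `muscle_fat_percent()` refuses an empty mask.

## Cobb angle geometry

Endplate annotations are two-point lines in the mid-sagittal plane, in mm,
with axis 1 craniocaudal and axis 2 antero-posterior. Each line's
inclination is taken against the antero-posterior axis and folded to
(−90°, 90°]; the Cobb angle is the absolute inclination difference,
reflected to [0°, 90°] when obtuse. Angles are between *undirected* lines:
the sign convention of a directed angle is never needed because thoracic
kyphosis cohorts (mean ≈ 39°, SD ≈ 13.5°) sit far from the 90° fold.
Whether the inferior line was drawn on T12-inferior or L1-superior is
recorded as provenance; the geometry is identical. Degenerate
(coincident-point) lines are rejected; parallel lines give exactly 0.

## The synthetic phantom

`generate_phantom()` builds a stated world, not a tunable one:

* **Compartments.** The nine bilateral groups are axis-aligned elliptic
  cylinders at nine craniocaudal stations, mirrored across the
  mid-sagittal plane. Anatomical realism is a non-goal: the downstream
  math (counting, thresholding, Dice, correlation) is geometry-agnostic,
  so only label topology, HU statistics and craniocaudal ordering are
  modeled.
* **Tissue model.** Muscle HU ~ N(+50, 10²), fat ~ N(−90, 10²),
  background −1000 (air), vertebrae +700. Both tissue distributions sit
  7 SD from the −20 HU threshold, so misclassification mass is Φ(−7) ≈
  1e−12 and planted-fraction recovery error is purely binomial; the spec
  constructor enforces at least 4 SD of margin. Each compartment voxel is
  independently fat with the group's planted probability, so measured
  fat% recovers the planted fraction within binomial sampling error
  (tests use 3 binomial SD) and recovers the *realized* fat voxel count
  exactly.
* **Spine.** A circular arc in the mid-sagittal plane whose tangent
  rotates by the planted Cobb angle between the T1-superior and
  T12-inferior stations. With tangent angle φ from the craniocaudal
  axis, the endplate (perpendicular to the tangent) makes angle φ with
  the antero-posterior axis, so the planted angle is recovered in closed
  form with no numerical fitting; the generated endplate lines are
  returned analytically (never rasterized), which is why recovery is
  exact to 1e−9° rather than merely < 0.5°. The sagittal bow is centered
  so its excursion splits evenly about the column's resting depth;
  configurations whose arc leaves the grid raise an error rather than
  clipping silently.

## The synthetic cohort

`generate_cohort()` plants a single latent "degeneration score"
z ~ N(0, 1) per case. Cobb and each muscle's fat% load on it:

$$\text{Cobb} = \mu_c + \sigma_c(\rho z + \sqrt{1-\rho^2}\,\varepsilon_0),
\qquad \text{fat}_m = \mu_m + \sigma_m(\lambda_m z +
\sqrt{1-\lambda_m^2}\,\varepsilon_m),$$

floored at 0 (and capped at 100). With the default ρ = 1 the planted
Pearson correlation of muscle m equals λ_m, attenuated slightly by the
floor: truncation bias is acknowledged rather than hidden, so recovery
tests compare against the planted value with a sampling-band tolerance
(±0.10 ≈ ±2/√421) instead of asserting the asymptotic λ exactly.

Defaults are the automated-cohort conditions: n = 433; Cobb
38.6 ± 13.5°; per-muscle fat% means/SDs at realistic cohort values
(paraspinal 15 ± 11%, rectus femoris ≈ 2 ± 2.3%, etc.); loadings equal to
the adjusted correlations the analysis targets (paraspinal λ = 0.42);
8 surgery + 4 atrophy confounders (12 in all, so exclusion leaves 421),
42 fracture and 20 transitional flags, 56.7% male. Distributional forms
(normal latent, truncated-normal fat%) are this module's modeling choice;
the source analysis does not state them.

Confounder mechanics mirror their real-world interpretations: surgery
*decouples* Cobb from z (independent redraw); atrophy replaces paraspinal
fat% by a uniform draw in (50, 90], independent of z — a high-leverage
decoupled outlier. Surgery and atrophy sets are drawn disjoint so the
exclusion union is exactly their sum. To keep the ">50% paraspinal"
rule exactly equivalent to the planted atrophy flag, chance extremes of
non-atrophy cases (≈ 3.2 SD events) are clamped at the 50% boundary — a
negligible distortion that buys an exact flag/rule correspondence.

Rater simulation adds `bias_j + e_ij`, `e_ij ~ N(0, σ_e²)` to true
angles. σ_e defaults to 3.69° so that the *expected sample SD* of k = 4
ratings matches the observed 3.4°: E[S] = σ·c₄(4) with c₄(4) =
√(2/3)·Γ(2)/Γ(1.5) ≈ 0.9213.

Every generator takes an explicit integer seed, restores the caller's RNG
state, and is bit-reproducible; no global random state is used.

What a green test does **not** establish: the phantom has no CT texture,
scanner/kernel effects, partial-volume mixing at muscle boundaries,
scoliosis/3D deformity, or anatomically shaped muscles. It validates the
*measurement code* under the statistical model the analysis assumes, not
the segmentation model or the biology.

## Reliability statistics

ICC(2,k) — two-way random effects, absolute agreement, reliability of the
k-rater mean — is computed from the ANOVA decomposition with rows = cases,
columns = raters:

$$\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}.$$

The implementation is direct sums of squares; the test oracle is an
independent `lm()`-based ANOVA, and agreement to 1e−10 is asserted over a
property sweep. Zero between-case variance makes the coefficient
undefined and raises an error rather than returning NaN.

Bootstrap CI: percentile method, resampling *cases* with replacement
(raters fixed), B = 2000 by default — the standard scheme for ICC; the
original B and scheme are not documented, so the CI is checked as a
width-order property (≈ 0.005–0.02 on the calibrated simulation), not an
equality. Degenerate replicates are skipped and counted. Per-case SD uses
ddof = 1 (stated explicitly since k = 4 is small). Bland–Altman differences
are taken against the own-case k-rater mean — so the bias is identically 0
(asserted) and the difference SD is σ_e·√(1−1/k) — with a single pooled
pair of limits of agreement (±1.96 SD).

## Segmentation metrics

Dice is `2|A∩B|/(|A|+|B|)`; both-empty pairs are defined as 1.0 with a
flag, so absent-muscle cases do not poison macro-averages, and one-empty
pairs are 0. The compound loss `L = L_Dice + L_CE` uses *global* soft Dice
(sums over classes and voxels jointly, the nnU-Net convention — the
per-class-averaged variant is available behind a flag for comparison) and
mean-reduced cross entropy with probabilities clipped at 1e−12. At a
perfect one-hot prediction both terms are exactly 0 (the ε in numerator
and denominator cancels).

## Correlation study

Pearson r with a two-sided p from the t transform with n−2 df; no
multiplicity correction (the analysis is exploratory and annotated as
such). Exclusions: surgery OR paraspinal fat% > 50 (the atrophy rule is
evaluated on the paraspinal muscle only; extreme values elsewhere do not
trigger it), logged once per case with all triggering rules;
muscle-specific ID lists (e.g. trapezius crop/absence) are a general
mechanism applied only to that muscle's analysis, in both raw and
adjusted cohorts by default since the original raw-column convention is
not documented. Strata with n < 3 are reported as undefined, never an
error. Exclusion is idempotent and r is invariant to affine rescaling of
either variable; both are asserted.

## Imaging I/O and preprocessing

NIfTI-1 single-file volumes (`.nii`/`.nii.gz`) are read and written by a
minimal in-package codec (float64 for HU volumes — exact round trips —
int16 for labels; both endiannesses on read; scl slope/intercept honored),
with arrays held in (z, y, x) order. Resampling to the model grid
(2.5 × 0.871 × 0.871 mm) uses separable Keys cubic convolution (a = −0.5)
in-plane and nearest neighbor along z for images; labels are nearest
neighbor on all axes and can therefore never acquire a label absent from
the input. Voxel-center alignment makes identity resampling exact and
constants are preserved (kernel rows sum to 1). Intensity preprocessing
clips to [−95, +116] HU and z-scores with the population SD of the
clipped volume. The clipping bounds are fixed constants: their
foreground-percentile derivation belongs to the segmentation framework's
internals and is out of scope.

## Known limitations

* The phantom's compartment geometry is deliberately schematic; Dice
  values on phantom derivatives exercise the metric code, not
  segmentation quality.
* Flooring fat% at 0 attenuates planted correlations for low-mean
  muscles; recovery tests use sampling-band tolerances for this reason.
* The NIfTI codec supports the subset of the format the pipeline emits;
  it is not a general-purpose reader (no 4D, no orientation repair, no
  DICOM).
* Real-data results that depend on the external imaging cohorts cannot
  be reproduced here; the test suite validates arithmetic targets,
  calibrated simulations and properties instead.
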