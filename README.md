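# kyphofat

Trunk muscle fat quantification and supine thoracic kyphosis analysis on
CT, with a synthetic phantom/cohort generator for end-to-end validation.

## What it is for

Thoracic kyphosis is measured by the Cobb angle — the angle between a
line parallel to the superior endplate of T1 and a line parallel to the
inferior endplate of T12/L1 on a mid-sagittal view. Manual Cobb
measurement is reliable but reader-intensive. CT muscle composition
offers an automatic complement: **muscle-fat%**, the percentage of voxels
within a segmented muscle with attenuation below −20 HU,

```
fat% = 100 · |{v ∈ mask : HU(v) < −20}| / |mask|
```

is an opportunistic biomarker of fatty muscle atrophy that correlates
with supine kyphosis, most strongly in the paraspinal extensors. This
package implements the quantitative pipeline behind that analysis for
researchers in opportunistic CT screening and musculoskeletal imaging:

* **`fat_quant`** — muscle-fat% and volume (mL) per bilateral muscle
  group from an HU volume + label map (nine trunk muscle groups, 18
  side-specific labels), with strict-below thresholding and voxel-pooled
  bilateral merging.
* **`cobb_geometry`** — Cobb angle from two-point endplate lines in the
  mid-sagittal plane (undirected lines, result in [0°, 90°]).
* **`reliability`** — ICC(2,k) (two-way random effects, absolute
  agreement) with case-resampling percentile bootstrap CI, Bland–Altman
  versus the k-rater mean, per-case SD and per-rater summaries.
* **`seg_metrics`** — Dice, macro-averages, and a reference
  implementation of the compound soft-Dice + cross-entropy training loss.
* **`cohort_analysis`** — confounder exclusion (spine surgery,
  paraspinal fat% > 50%), Pearson correlation tables (raw vs adjusted),
  sex stratification and fracture/transitional sensitivity analyses.
* **`phantom`** — synthetic CT phantom (known fat fractions, closed-form
  Cobb ground truth) and cohort/rater generators calibrated to the
  cohort's published summary statistics, so the full pipeline runs and
  validates with no external data.
* **`imaging_io`** — minimal NIfTI-1 I/O, resampling to the
  2.5 × 0.871 × 0.871 mm model grid (cubic in-plane, nearest along z),
  and the clip(−95, 116) + z-score model-input transform.

See `vignettes/methods.Rmd` for the model, assumptions, and numerical
choices.

## Worked example

```r
library(kyphofat)

# A phantom with known ground truth: planted Cobb 38.6 deg, realistic
# per-muscle fat fractions (paraspinal 15%, rectus femoris 2.1%, ...)
ph <- generate_phantom(phantom_spec(seed = 42))
quantify_all(ph$volume, ph$labels)
#>                group present n_voxels n_fat_voxels fat_percent volume_mL
#> 1              psoas    TRUE     4860          253       5.206     9.217
#> 3         paraspinal    TRUE     4860          774      15.926     9.217
#> 8          trapezius    TRUE     4860           91       1.872     9.217
#> ...                                                           (9 rows)
cobb_angle(ph$endplates)
#> Cobb angle: 38.60 deg (superior endplate -19.30, inferior 19.30)
```

The measured fat% (e.g. paraspinal 15.93%) recovers the planted fraction
(15%) within binomial sampling error of the ~9,700-voxel compartment, and
the endplate-based Cobb angle recovers the planted arc rotation exactly.

```r
# A 433-case synthetic cohort + four raters, calibrated to the published
# reliability summaries (Cobb 38.6 +/- 13.5 deg, per-case SD 3.4 deg)
co <- generate_cohort(cohort_spec(seed = 42))
m  <- simulate_raters(co$cobb_mean, rater_noise_spec(seed = 43))
bootstrap_ci(m, B = 2000, seed = 44)
#> ICC(2,k): 0.9796  (n = 433 cases, k = 4 raters)
#>   bootstrap 95% CI: [0.9759, 0.9824]  (B = 2000)

# Raw vs confounder-adjusted correlation (12 confounded cases excluded)
tab <- run_table(co)
tab[tab$muscle == "paraspinal", ]
#>    cohort_label     muscle     r p_two_sided n_used
#> 3           raw paraspinal 0.333    1.07e-12    433
#> 12     adjusted paraspinal 0.400    1.26e-17    421
```

Exclusion of the planted surgery/atrophy confounders raises the
paraspinal correlation toward its planted value (λ = 0.42), mirroring the
raw-vs-adjusted pattern of the real analysis.

A single JSON config drives the whole pipeline (`run_pipeline()` /
`kyphofat run --config cfg.json`), writing phantom NIfTIs, metrics,
Cobb, reliability and correlation tables plus a config snapshot and
version manifest; re-runs are bit-identical. A CLI wrapper with
subcommands `phantom`, `io`, `quantify`, `cobb`, `reliability`,
`segmetrics`, `cohort`, `run` is installed at `inst/cli/kyphofat` and
available in R via `kyphofat_cli()`.

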