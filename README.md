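# braincase

Single-subject normative comparison of structural-MRI biomarkers.

Clinical questions about neurodegeneration are usually questions about *one*
patient, but most morphometry pipelines only compare groups. `braincase`
implements the single-case route: one subject's regional biomarkers
(subcortical volume, cortical thickness, surface area, curvature, global
GM/WM volume) and voxel-wise gray-matter maps are tested against a small,
age-matched normative control sample, and the resulting per-patient atrophy
maps can be aggregated into group probability-overlap maps, region-wise
atrophy prevalence, disease-burden correlations and longitudinal atrophy
rates. The intended users are neuroimaging researchers studying
neurodegenerative disease (the built-in region panel targets Huntington's
disease) who already have segmented/registered data and need calibrated
single-subject statistics.

## The statistics

The core inferential tool is the **Crawford–Howell modified t-test** for
comparing a single observation `x*` with a normative sample of size `n`
(mean `x̄`, sample SD `s`):

```
t = (x* − x̄) / (s · √((n+1)/n)),   df = n − 1
```

Unlike the naive z-score — which treats `x̄` and `s` as population values
and over-rejects badly for small `n` — this statistic follows an exact
Student t distribution under the null for any `n ≥ 2`. The package always
reports both `z` and `t`; significance decisions use `t`.

Around that core:

* **Normative cohort construction** — controls within the subject's age ± 10
  years (configurable, closed interval), optional normalization of
  head-size-dependent measures by total intracranial volume (TIV).
* **Region panels** — Benjamini–Hochberg FDR across the panel
  (`q = 0.05`, significant when adjusted p < 0.05); the HD panel covers the
  caudate, putamen, accumbens area and ventricles bilaterally, seven
  cortical regions per hemisphere, and global GM/WM.
* **Voxel-wise maps** — the same t-test per voxel on co-registered,
  modulated gray-matter images after mass-conserving Gaussian smoothing;
  one-tailed for atrophy by default; binarized at p < 0.005 uncorrected.
* **Group aggregation** — probability overlap maps (sum of binary maps / n)
  with 75%/90% consensus thresholds; atrophy prevalence within region
  masks; affected-voxel counts.
* **Clinical coupling** — HD disease burden `Age × (CAG − 35.5)`, Pearson
  and first-order partial correlations (residual method), annualized
  atrophy rates (OLS slope) and pooled-variance group rate comparison.
* **Synthetic data** — a fully seeded generator for metadata, ROI tables
  and 3-D gray-matter images with implanted deficits, used throughout the
  tests.

## Worked example

```r
library(braincase)

# a seeded synthetic cohort: 20 controls + 1 patient whose left caudate
# is implanted 5 SD below the normative mean
cfg <- simulation_config(
  seed = 5, n_controls = 20, n_patients = 1,
  implants_roi = tibble::tibble(
    subject_id = "pat001", region = "Left-Caudate",
    measure = "volume_mm3", effect_sd = -5
  )
)
sim <- simulate_cohort(cfg)

cmp <- compare_roi_panel(
  subject_records = dplyr::filter(sim$records, subject_id == "pat001"),
  control_records = dplyr::filter(sim$records, subject_id != "pat001"),
  controls_meta  = dplyr::filter(sim$meta, group == "control"),
  panel = hd_panel(),
  subject_age = sim$meta$age[sim$meta$subject_id == "pat001"]
)
dplyr::filter(tidy(cmp), significant)
#>         region    measure n_controls control_mean control_sd      z      t df
#> 1 Left-Caudate volume_mm3          9     0.002253  0.0001506 -7.005 -6.646  8
#>           p    p_adj significant direction
#> 1 0.0001615 0.003876        TRUE     below
```

Only the implanted biomarker survives FDR over the 24-key panel
(`p_adj ≈ 0.0039 < 0.05`) with direction `below`. The control mean and SD
are on the TIV-normalized scale (volume / TIV), and `n_controls = 9`
because only nine simulated controls fall inside this 55.5-year-old
subject's ± 10-year age window. `glance(cmp)` summarizes the panel,
`autoplot(cmp)` draws the deviation profile, and
`write_report(tidy(cmp), "report.csv", "csv")` serializes it.

The voxel-wise branch is analogous
(`voxelwise_single_case()` → `threshold_binarize()` →
`overlap_probability_map()` / `region_atrophy_prevalence()`), and
`inst/cli/braincase.R` exposes both branches plus simulation as shell
subcommands (`roi-compare`, `vbm-compare`, `overlap`, `longitudinal`,
`clinical`, `simulate`).

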