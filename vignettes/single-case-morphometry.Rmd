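---
title: "Single-case normative morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-case normative morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincase)
```

## The inferential problem

Group studies of neurodegeneration average away exactly the thing a
clinician needs: where *this* patient deviates from what is expected. The
single-case framing replaces the two-sample comparison with a test of one
observation `x*` against a normative sample — the controls closest in age
to the patient. Two statistics are computed for every biomarker:

* the **z-score** `(x* − x̄)/s`, descriptive and familiar, but
  anti-conservative when the control sample is small because it treats the
  sample mean and SD as population values;
* the **Crawford–Howell modified t**,
  `t = (x* − x̄)/(s√((n+1)/n))` on `n − 1` degrees of freedom, which
  follows an exact Student t distribution under the null for any `n ≥ 2`.

Both are always reported; significance decisions use the modified t. The
`√((n+1)/n)` inflation accounts for the case observation being compared
with an *estimated* mean; as `n → ∞`, `t → z`. The test suite quantifies
the difference: with ten controls the modified t rejects at the nominal 5%
rate, while `|z| > 1.96` with five controls rejects about 15% of the time.

### Assumptions

The modified t assumes the normative values are approximately Gaussian and
exchangeable with the case under the null. Heavy-tailed or skewed
biomarker distributions (and very small cohorts) break the calibration;
the package flags cohorts below five controls with a warning and refuses
cohorts below two, where the SD is undefined.

## Building the normative cohort

Controls are retained when their age lies in the closed interval
`subject age ± deviation`; the default deviation is 10 years, a
conventional compromise between age matching and cohort size. The bounds
are inclusive because "±" reads most naturally as a closed interval, and
the convention is then testable at the boundary. Only age is a matching
variable; any other matching (sex, education) is achieved by pre-filtering
the control metadata before the comparison.

Head-size-dependent measures (volumes, surface areas, global GM/WM,
ventricles) can be normalized by total intracranial volume. We use plain
division (the proportion method) rather than covariate regression: it is
the minimal, assumption-free adjustment, it is flagged in every report,
and the regression alternative would require a normative model this
package deliberately does not fit. Thickness and curvature do not scale
with head size and pass through untouched; re-normalizing an already
normalized table is an error rather than a silent second division.

## The region panel and multiplicity

Testing a disease-driven panel rather than every parcellated region keeps
the multiple-comparison burden small. The built-in Huntington's disease
panel contains the bilateral caudate, putamen, accumbens area and lateral
ventricles (volume), seven cortical regions per hemisphere (thickness),
and global GM/WM volume — 24 keys. Benjamini–Hochberg FDR is applied once
across the whole panel (`m` = panel size); a biomarker is significant when
its adjusted p is strictly below `alpha = 0.05`. Two-tailed p-values are
the panel default because both losses (atrophy) and gains (ventricular
enlargement) are clinically meaningful; the voxel-wise branch defaults to
one-tailed "less" because its downstream aggregation counts atrophy only.

## The voxel-wise branch

The whole-brain branch consumes spatially registered, modulated
gray-matter images — registration, segmentation and modulation are
upstream tools' responsibility, and no resampling or reorientation is ever
performed: images entering a group operation must share the grid and
affine exactly (tolerance 1e-4).

**Smoothing.** Separable Gaussian smoothing with per-axis sigma
`FWHM/(2√(2 ln 2))/voxel_size`, applied identically to the case and every
control — unequal smoothing would break exchangeability under the null.
Convolution is circular with a unit-sum kernel, so the total image mass
(which encodes volume in modulated images) is conserved exactly; with a
zero background at the image border, circular wrap-around is numerically
indistinguishable from zero padding while keeping conservation exact. The
default kernel is 8 mm FWHM, the common choice for this resolution of
analysis; 0 disables smoothing.

**Masking.** The analysis mask keeps voxels where the mean control
intensity is at least `gm_floor = 0.1` (excludes background/non-GM in
tissue-probability units) and the control SD is at least
`sd_floor = 1e-6` (excludes voxels where the t statistic is undefined).
Both floors are package decisions — there is no canonical value — and both
are recorded in the output metadata.

**Testing and binarization.** Per in-mask voxel, the same modified t with
`n` = number of controls. Maps are binarized at an uncorrected `p < 0.005`
(strict), the conventional exploratory threshold; no cluster-extent or
random-field correction is applied, and the p maps say so. The vectorized
implementation is required to agree with the scalar test voxel-by-voxel to
1e-10, which the suite checks at 100 random voxels.

## Group aggregation

Binary maps are summed and divided by the number of subjects, giving the
voxel-wise fraction of patients with atrophy. Consensus thresholds are
inclusive (`≥ 0.75` keeps a voxel present in exactly 75% of subjects) —
the natural reading of "75% of patients" and the convention that makes the
3-of-4 example well defined. A subject counts as atrophic within a region
mask when at least one suprathreshold voxel falls inside it
(`min_voxels = 1`, configurable); "either region A or B" prevalence is
obtained by passing the union mask.

## Clinical and longitudinal analyses

The HD disease burden is `Age × (CAG − 35.5)`; values for CAG below 35.5
are allowed but flagged, since they fall outside the pathological
expansion range. Correlations between imaging and clinical measures use
Pearson's r; partial correlations controlling for disease burden use the
first-order recursion formula, which the suite requires to match the
residual-regression construction to 1e-10. Correlation p-values in this
module are descriptive and deliberately not FDR-corrected.

Annualized rates use the OLS slope of value on time-in-years, which
reduces exactly to the two-point difference quotient for two sessions —
the estimator is stated nowhere in the underlying designs, and OLS is the
least surprising choice that handles more than two sessions. Group rate
comparisons default to the pooled-variance Student t (with a Welch
option), recording the variant in the output.

## The synthetic-data generator

The generator is first-class, tested code; it emulates every input the
pipeline consumes:

* **Cohorts** — 33 controls and 42 patients by default, ages uniform on
  25–65 years and patient CAG uniform on 40–48, mirroring a typical
  single-center HD-versus-control study (controls around 45 ± 11 years,
  CAG around 44 ± 3); TIV is Normal(1.5·10⁶, 1.2·10⁵) mm³ truncated
  positive, and head-size-dependent measures scale with each subject's
  TIV so that TIV normalization genuinely reduces normative variance.
* **ROI tables** — Gaussian biomarkers at FreeSurfer-typical means/SDs
  with mild linear age trends; implanted deficits shift a subject's
  generating mean by `effect_sd × SD`.
* **Images** — a shared template (filled ellipsoid at intensity 0.8, or a
  seeded smooth random field) plus per-subject Gaussian noise
  (SD 0.1 in tissue-probability units); implanted spheres subtract
  `effect_sd × noise SD`, clipped at zero.

Each subject draws from an RNG stream derived from (seed, subject index),
so enlarging a cohort never reshuffles existing subjects. What the
generator does *not* emulate: spatial autocorrelation of real GM maps,
registration error, partial-volume effects, non-Gaussian biomarker tails,
and realistic anatomy. Passing tests therefore demonstrate statistical
correctness and calibration of the machinery under the stated model — not
robustness to the artifacts of real data.

## Numerical choices and degenerate inputs

* p-values from the t CDF; the suite checks them against an independent
  incomplete-beta formulation to 1e-6 over 1,000 random cases.
* Degenerate cohorts (SD = 0) are flagged and refuse to produce z or t.
* BH ties are handled by the monotone step, so equal p-values always get
  equal adjusted values; rejection uses strict inequality (`p_adj < q`).
* `direction` is `none` exactly when `t = 0`; otherwise the sign of
  `x* − x̄` decides `below`/`above`.
* Voxel indexing is 0-based through the NIfTI affine; world coordinates
  come only from the affine, and mismatched grids are an error, never an
  implicit resample.
* Report serialization keeps full double precision (≥ 10 significant
  digits), so reports round-trip and reruns are byte-identical.

## Problem sizes used in the checks

The self-checks run on sizes chosen to make Monte-Carlo error small while
keeping a laptop-friendly footprint: 10,000 replicates for type-I
calibration, 500 cohort replicates for the panel pipeline, fifty 32³ null
images for voxel-wise calibration, twenty seeds for sphere recovery
(radius 6 voxels, −4 SD, 20 controls, 2-voxel FWHM), and 1,000 random
cases for each oracle-equivalence bound.

One calibration detail: the voxel-wise null-calibration check runs with
smoothing disabled. Smoothing leaves the per-voxel null distribution exact
(case and controls are smoothed identically) but correlates neighboring
voxels, so the binomial error bar used by the check would be too narrow;
disabling smoothing makes voxels independent and the bound honest.

## Known limitations

* No covariate-adjusted normative modelling (age enters only through the
  selection window, not as a regression term).
* No cluster-level inference or random-field correction in the voxel-wise
  branch.
* The pooled t for rate comparisons assumes equal variances; the Welch
  flag exists but mixed-effects longitudinal modelling is out of scope.
* Single-case inference inherits the usual caveats for small normative
  samples: non-normal control distributions distort p-values, and
  a cohort below ~5 controls gives very wide implicit intervals.
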