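#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: cohort sizes and
#' demographics, the ROI biomarker panel with generating means/SDs and age
#' trends, ROI-level implanted deficits, the 3-D image grid, template and
#' noise level, and voxel-level implanted atrophy spheres. Identical
#' seed + configuration always produces identical output; each subject has
#' their own RNG stream derived from (seed, subject index), so growing the
#' cohort never reshuffles earlier subjects.
#'
#' Defaults mirror a typical single-center HD-versus-control structural MRI
#' study: 33 controls and 42 gene carriers, ages 25-65 years, CAG repeat
#' lengths 40-48, FreeSurfer-scale ROI means/SDs, and 2 mm isotropic
#' 32x32x32 gray-matter grids with noise SD 0.1 in tissue-probability
#' units.
#'
#' @param seed integer RNG seed.
#' @param n_controls,n_patients cohort sizes.
#' @param age_range ages are drawn uniformly from this range (years).
#' @param roi_panel tibble with columns `region`, `measure`, `mean`, `sd`
#'   and optionally `age_slope` (units per year, centred at mid-range age).
#' @param implants_roi `NULL` or tibble with columns `subject_id`,
#'   `region`, `measure`, `effect_sd`: the named subject's generating mean
#'   for that biomarker is shifted by `effect_sd * sd`.
#' @param grid_shape,voxel_size 3-D image grid (voxels, mm).
#' @param gm_template `"ellipsoid_shell"` (filled ellipsoid of intensity
#'   0.8) or `"smooth_field"` (seeded smooth random field in `[0, 1]`).
#' @param image_noise_sd per-voxel Gaussian noise SD added per subject.
#' @param implants_voxel `NULL` or tibble with columns `subject_id`, `cx`,
#'   `cy`, `cz` (0-based voxel center), `radius` (voxels) and `effect_sd`:
#'   intensity inside the sphere is lowered by `effect_sd * image_noise_sd`
#'   and clipped at 0.
#' @param cag_range patients' CAG repeat lengths are uniform integers in
#'   this range.
#' @param tiv_mean,tiv_sd total-intracranial-volume distribution (mm^3),
#'   truncated positive.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_controls = 33L, n_patients = 42L,
                              age_range = c(25, 65),
                              roi_panel = default_roi_panel(),
                              implants_roi = NULL,
                              grid_shape = c(32L, 32L, 32L),
                              voxel_size = c(2, 2, 2),
                              gm_template = c("ellipsoid_shell", "smooth_field"),
                              image_noise_sd = 0.1,
                              implants_voxel = NULL,
                              cag_range = c(40L, 48L),
                              tiv_mean = 1.5e6, tiv_sd = 1.2e5) {
  gm_template <- match.arg(gm_template)
  stopifnot(
    n_controls >= 0, n_patients >= 0,
    length(age_range) == 2, age_range[1] < age_range[2],
    all(c("region", "measure", "mean", "sd") %in% names(roi_panel)),
    length(grid_shape) == 3, all(grid_shape >= 1),
    length(voxel_size) == 3, all(voxel_size > 0),
    image_noise_sd >= 0, tiv_mean > 0, tiv_sd >= 0
  )
  if (!is.null(implants_voxel) && nrow(implants_voxel) > 0 &&
      any(implants_voxel$radius >= min(grid_shape) / 2)) {
    abort("implant radius must be smaller than half the smallest grid dimension.")
  }
  if (!"age_slope" %in% names(roi_panel)) roi_panel$age_slope <- 0
  structure(
    list(
      seed = as.integer(seed), n_controls = as.integer(n_controls),
      n_patients = as.integer(n_patients), age_range = age_range,
      roi_panel = roi_panel, implants_roi = implants_roi,
      grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
      gm_template = gm_template, image_noise_sd = image_noise_sd,
      implants_voxel = implants_voxel, cag_range = cag_range,
      tiv_mean = tiv_mean, tiv_sd = tiv_sd
    ),
    class = "simulation_config"
  )
}

#' Default generating panel for the synthetic cohort
#'
#' FreeSurfer-scale means and SDs for the HD target panel: subcortical
#' volumes in mm^3, cortical thickness in mm, global GM/WM volume in mm^3,
#' with mild age trends (volume loss and cortical thinning per year,
#' ventricular enlargement).
#'
#' @return A tibble with `region`, `measure`, `mean`, `sd`, `age_slope`.
#' @export
default_roi_panel <- function() {
  sub <- tibble::tribble(
    ~region,                   ~mean,  ~sd,   ~age_slope,
    "Left-Caudate",             3500,   400,   -10,
    "Right-Caudate",            3550,   400,   -10,
    "Left-Putamen",             4800,   500,   -15,
    "Right-Putamen",            4850,   500,   -15,
    "Left-Accumbens-area",       600,    90,    -2,
    "Right-Accumbens-area",      620,    90,    -2,
    "Left-Lateral-Ventricle",   8000,  3000,   120,
    "Right-Lateral-Ventricle",  7600,  3000,   120
  )
  sub$measure <- "volume_mm3"
  cort_names <- c(
    "precentral", "postcentral", "superiorfrontal", "inferiorparietal",
    "superiorparietal", "insula", "medialorbitofrontal"
  )
  cort_means <- c(2.55, 2.05, 2.70, 2.45, 2.20, 3.00, 2.40)
  cort <- tibble::tibble(
    region = c(paste0("lh-", cort_names), paste0("rh-", cort_names)),
    measure = "thickness_mm",
    mean = rep(cort_means, 2), sd = 0.12, age_slope = -0.005
  )
  glob <- tibble::tibble(
    region = "Global",
    measure = c("gm_total_mm3", "wm_total_mm3"),
    mean = c(650000, 480000), sd = c(55000, 45000),
    age_slope = c(-2000, -1000)
  )
  dplyr::bind_rows(sub[, c("region", "measure", "mean", "sd", "age_slope")],
                   cort, glob)
}

# Per-subject RNG stream seed: stable under cohort-size changes.
subject_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 7919 * idx) %% 2147483647)
}

#' Simulate a control/patient cohort with ROI biomarkers
#'
#' Control biomarkers are drawn from
#' `Normal(mean + age_slope * (age - midrange), sd)`; patient biomarkers
#' are additionally shifted by `effect_sd * sd` for every entry of
#' `config$implants_roi` matching that subject. Head-size-dependent
#' measures are scaled by each subject's TIV relative to the population
#' mean, so TIV normalization meaningfully reduces normative variance.
#' Ages are uniform over `age_range`; CAG repeat lengths are uniform
#' integers over `cag_range` for patients.
#'
#' @param config a [simulation_config()].
#' @return A list with `meta` (subject metadata tibble) and `records`
#'   (biomarker record tibble including per-subject `etiv_mm3`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- config$roi_panel
  mid_age <- mean(config$age_range)
  n_total <- config$n_controls + config$n_patients
  ids <- c(
    sprintf("ctrl%03d", seq_len(config$n_controls)),
    sprintf("pat%03d", seq_len(config$n_patients))
  )
  groups <- rep(c("control", "patient"),
                c(config$n_controls, config$n_patients))

  meta_rows <- vector("list", n_total)
  rec_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(subject_seed(config$seed, i))
    age <- runif(1, config$age_range[1], config$age_range[2])
    sex <- sample(c("f", "m"), 1)
    cag <- if (groups[i] == "patient") {
      sample(seq(config$cag_range[1], config$cag_range[2]), 1)
    } else {
      NA_integer_
    }
    tiv <- config$tiv_mean
    if (config$tiv_sd > 0) {
      repeat {
        tiv <- rnorm(1, config$tiv_mean, config$tiv_sd)
        if (tiv > 0) break
      }
    }

    mu <- panel$mean + panel$age_slope * (age - mid_age)
    if (groups[i] == "patient" && !is.null(config$implants_roi)) {
      imp <- config$implants_roi[config$implants_roi$subject_id == ids[i], ,
                                 drop = FALSE]
      if (nrow(imp) > 0) {
        j <- match(paste(imp$region, imp$measure),
                   paste(panel$region, panel$measure))
        if (any(is.na(j))) {
          abort("implants_roi names a biomarker absent from roi_panel.")
        }
        mu[j] <- mu[j] + imp$effect_sd * panel$sd[j]
      }
    }
    values <- rnorm(nrow(panel), mu, panel$sd)
    scale_tiv <- panel$measure %in% TIV_SCALED_MEASURES
    values[scale_tiv] <- values[scale_tiv] * (tiv / config$tiv_mean)

    meta_rows[[i]] <- tibble::tibble(
      subject_id = ids[i], group = groups[i], age = age, sex = sex, cag = cag
    )
    rec_rows[[i]] <- tibble::tibble(
      subject_id = ids[i], session = 1L,
      region = c(panel$region, "Global"),
      measure = c(panel$measure, "etiv_mm3"),
      value = c(values, tiv),
      normalized = FALSE
    )
  }
  list(meta = dplyr::bind_rows(meta_rows),
       records = dplyr::bind_rows(rec_rows))
}

#' Simulate co-registered gray-matter images
#'
#' All subjects share one template on one affine; each subject adds their
#' own Gaussian voxel noise, and subjects listed in
#' `config$implants_voxel` get a spherical intensity reduction of
#' `effect_sd * image_noise_sd` (clipped at 0) — implanted focal atrophy.
#'
#' @param config a [simulation_config()].
#' @return A named list of [volume_image()]s (controls `ctrl...`, then
#'   patients `pat...`), with the noiseless template attached as attribute
#'   `"template"`.
#' @export
simulate_gm_images <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  shape <- config$grid_shape
  template <- make_gm_template(config)
  affine <- diag(c(config$voxel_size, 1))

  if (!is.null(config$implants_voxel) && nrow(config$implants_voxel) > 0) {
    iv <- config$implants_voxel
    lo <- pmin(iv$cx - iv$radius, iv$cy - iv$radius, iv$cz - iv$radius)
    hi_ok <- iv$cx + iv$radius <= shape[1] - 1 &
      iv$cy + iv$radius <= shape[2] - 1 &
      iv$cz + iv$radius <= shape[3] - 1
    if (any(lo < 0) || !all(hi_ok)) {
      abort("an implant sphere extends outside the image grid.")
    }
  }

  ids <- c(
    sprintf("ctrl%03d", seq_len(config$n_controls)),
    sprintf("pat%03d", seq_len(config$n_patients))
  )
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    set.seed(subject_seed(config$seed, 100000L + i))
    dat <- template
    if (config$image_noise_sd > 0) {
      dat <- dat + array(rnorm(prod(shape), 0, config$image_noise_sd), shape)
    }
    if (!is.null(config$implants_voxel)) {
      imp <- config$implants_voxel[
        config$implants_voxel$subject_id == ids[i], , drop = FALSE
      ]
      for (k in seq_len(nrow(imp))) {
        sph <- sphere_mask(shape, c(imp$cx[k], imp$cy[k], imp$cz[k]),
                           imp$radius[k])
        dat[sph] <- dat[sph] - imp$effect_sd[k] * config$image_noise_sd
      }
    }
    dat[dat < 0] <- 0
    out[[i]] <- volume_image(dat, affine = affine)
  }
  attr(out, "template") <- volume_image(template, affine = affine)
  out
}

# Shared noiseless template. ellipsoid_shell: filled ellipsoid with
# semi-axes at 40% of the grid, intensity 0.8; smooth_field: seeded white
# noise smoothed to ~2-voxel correlation length and rescaled to [0, 1].
make_gm_template <- function(config) {
  shape <- config$grid_shape
  if (config$gm_template == "ellipsoid_shell") {
    cx <- (shape - 1) / 2
    ax <- pmax(shape * 0.4, 1)
    g <- expand.grid(
      x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
      z = seq_len(shape[3]) - 1
    )
    r2 <- ((g$x - cx[1]) / ax[1])^2 + ((g$y - cx[2]) / ax[2])^2 +
      ((g$z - cx[3]) / ax[3])^2
    array(0.8 * (r2 <= 1), shape)
  } else {
    set.seed(config$seed)
    x <- array(rnorm(prod(shape)), shape)
    for (axis in 1:3) x <- convolve_axis_circular(x, axis, 2)
    rng <- range(x)
    (x - rng[1]) / (rng[2] - rng[1])
  }
}

# Logical sphere mask; center is a 0-based voxel index triplet.
sphere_mask <- function(shape, center, radius) {
  g <- expand.grid(
    x = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
    z = seq_len(shape[3]) - 1
  )
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, shape)
}

#' Simulate longitudinal biomarker series
#'
#' `value(session s) = baseline + rate * t_s / 12 + noise`, with sessions
#' at `0, interval_months, 2 * interval_months, ...` from baseline.
#'
#' @param config a [simulation_config()] (supplies the seed).
#' @param rates named numeric vector, subject id -> rate per year.
#' @param n_sessions number of sessions (>= 2).
#' @param interval_months spacing between sessions in months.
#' @param baseline baseline value (single number or named per subject).
#' @param noise_sd per-observation Gaussian noise SD.
#' @param region,measure biomarker key stamped on the output.
#' @return A long tibble: `subject_id`, `region`, `measure`, `session`,
#'   `interval_months`, `value`.
#' @export
simulate_longitudinal <- function(config, rates, n_sessions = 2L,
                                  interval_months = 18, baseline = 4000,
                                  noise_sd = 0, region = "Right-Putamen",
                                  measure = "volume_mm3") {
  stopifnot(inherits(config, "simulation_config"), n_sessions >= 2)
  ids <- names(rates)
  if (is.null(ids)) {
    ids <- sprintf("subj%03d", seq_along(rates))
    names(rates) <- ids
  }
  if (length(baseline) == 1L) {
    baseline <- setNames(rep(baseline, length(ids)), ids)
  }
  t_months <- (seq_len(n_sessions) - 1) * interval_months
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(subject_seed(config$seed, 200000L + i))
    noise <- if (noise_sd > 0) rnorm(n_sessions, 0, noise_sd) else 0
    rows[[i]] <- tibble::tibble(
      subject_id = ids[i], region = region, measure = measure,
      session = seq_len(n_sessions),
      interval_months = t_months,
      value = baseline[ids[i]] + rates[ids[i]] * t_months / 12 + noise
    )
  }
  dplyr::bind_rows(rows)
}
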