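# Fixtures are built in code at test time; nothing binary is stored.

write_aseg_fixture <- function(path,
                               rows = list(
                                 c(seg = 11, vol = 3512.0, name = "Left-Caudate"),
                                 c(seg = 50, vol = 3488.5, name = "Right-Caudate")
                               ),
                               etiv = 1534363.0,
                               extra_measures = TRUE) {
  lines <- c(
    "# Title Segmentation Statistics",
    "# subjectname fixture",
    sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %f, mm^3", etiv)
  )
  if (extra_measures) {
    lines <- c(
      lines,
      # Cortex is deliberately not in the recognized set: must be ignored
      "# Measure Cortex, CortexVol, Total cortical gray matter volume, 450000.0, mm^3",
      "# Measure TotalGrayVol, TotalGray, Total gray matter volume, 651234.5, mm^3",
      "# Measure CerebralWhiteMatterVol, CerebralWhiteMatter, Total cerebral white matter volume, 480321.0, mm^3",
      "# Measure VentricleChoroidVol, VentricleChoroidVol, Volume of ventricles and choroid plexus, 15222.0, mm^3"
    )
  }
  lines <- c(
    lines,
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean",
    vapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      sprintf("  %d %s 3000 %s %s 80.1", i, r[["seg"]], r[["vol"]], r[["name"]])
    }, character(1))
  )
  writeLines(lines, path)
  path
}

write_aparc_fixture <- function(path, hemi = "lh",
                                rows = list(
                                  c(name = "precentral", area = 8210,
                                    vol = 13050, thick = 2.51, curv = 0.12),
                                  c(name = "insula", area = 2244,
                                    vol = 6890, thick = 3.02, curv = 0.15)
                                )) {
  lines <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    sprintf("# hemi %s", hemi),
    "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv",
    vapply(rows, function(r) {
      sprintf("%s 12000 %s %s %s 0.5 %s",
              r[["name"]], r[["area"]], r[["vol"]], r[["thick"]], r[["curv"]])
    }, character(1))
  )
  writeLines(lines, path)
  path
}

# Small helper: volume image filled with given values on a unit grid.
vol_from <- function(values, shape = c(4, 4, 4), voxel = c(1, 1, 1)) {
  volume_image(array(values, shape), voxel_size = voxel)
}

# Wrap a 0/1 volume image as a binary_map like threshold_binarize() makes.
as_binary_map <- function(img, direction = "less") {
  structure(
    list(data = img, threshold_p = 0.005, direction = direction),
    class = "binary_map"
  )
}

# Independent high-precision Student-t CDF via the regularized incomplete
# beta function; used as the oracle for Crawford-Howell p-values.
t_cdf_oracle <- function(t, df) {
  x <- df / (df + t^2)
  half <- 0.5 * pbeta(x, df / 2, 0.5)
  ifelse(t <= 0, half, 1 - half)
}

# Brute-force Benjamini-Hochberg step-up: literal definition, quadratic.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted value = min over j >= i of p_(j) * m / j, capped at 1
    js <- i:m
    adj[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  adj
}

# Small normative cohort object without going through build_cohort().
mini_cohort <- function(values) {
  list(
    region = "r", measure = "volume_mm3", values = values,
    control_ids = paste0("c", seq_along(values)), n = length(values),
    mean = mean(values), sd = sd(values),
    age_window = c(0, 100), normalized = FALSE, degenerate = sd(values) == 0
  )
}
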