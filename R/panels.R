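#' Panel-name aliases for bilateral region groups
#'
#' Region names are kept verbatim from the segmentation tables
#' (e.g. `"Left-Caudate"`); this alias table maps the short panel names
#' used in disease definitions to the verbatim names, so a panel entry
#' like `"caudate"` expands to both hemispheres without lossy renaming.
#'
#' @return A tibble with columns `alias` and `region`.
#' @export
region_aliases <- function() {
  tibble::tribble(
    ~alias,        ~region,
    "caudate",     "Left-Caudate",
    "caudate",     "Right-Caudate",
    "putamen",     "Left-Putamen",
    "putamen",     "Right-Putamen",
    "accumbens",   "Left-Accumbens-area",
    "accumbens",   "Right-Accumbens-area",
    "ventricles",  "Left-Lateral-Ventricle",
    "ventricles",  "Right-Lateral-Ventricle"
  )
}

#' Disease-specific region panel for Huntington's disease
#'
#' The predefined target panel for HD: subcortical volumes of the caudate,
#' putamen, accumbens area and lateral ventricles (bilaterally), cortical
#' thickness of the precentral, postcentral, superior frontal, inferior and
#' superior parietal, insula and medial orbitofrontal regions (both
#' hemispheres), and global gray- and white-matter volume. Restricting the
#' comparison to a disease-driven panel keeps the multiple-comparison
#' burden small.
#'
#' @param include_cortical include the cortical-thickness entries.
#' @param include_global include global GM/WM volume.
#' @return A tibble with columns `region` and `measure`.
#' @export
hd_panel <- function(include_cortical = TRUE, include_global = TRUE) {
  sub <- tibble::tibble(
    region = region_aliases()$region,
    measure = "volume_mm3"
  )
  out <- sub
  if (include_cortical) {
    cort_names <- c(
      "precentral", "postcentral", "superiorfrontal", "inferiorparietal",
      "superiorparietal", "insula", "medialorbitofrontal"
    )
    cort <- tibble::tibble(
      region = c(paste0("lh-", cort_names), paste0("rh-", cort_names)),
      measure = "thickness_mm"
    )
    out <- dplyr::bind_rows(out, cort)
  }
  if (include_global) {
    glob <- tibble::tibble(
      region = "Global",
      measure = c("gm_total_mm3", "wm_total_mm3")
    )
    out <- dplyr::bind_rows(out, glob)
  }
  out
}
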