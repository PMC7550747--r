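#' Probability overlap map of binarized atrophy patterns
#'
#' Adds the subjects' binary neurodegeneration maps together and normalizes
#' by the number of subjects, giving at each voxel the fraction of subjects
#' whose thresholded single-case map marks it as atrophic.
#'
#' @param binaries list of `binary_map` objects (see
#'   [threshold_binarize()]) on a common grid.
#' @param ids optional character vector of contributing subject ids.
#' @return An `overlap_map`: `probability` volume image in `[0, 1]`,
#'   `n_subjects` and `contributing_ids`.
#' @export
overlap_probability_map <- function(binaries, ids = NULL) {
  if (length(binaries) < 1) abort("at least one binary map is required.")
  vols <- lapply(binaries, function(b) b$data)
  check_common_grid(vols, names = paste0("binary map ", seq_along(vols)))
  total <- Reduce(`+`, lapply(vols, function(v) v$data))
  out <- vols[[1]]
  out$data <- total / length(binaries)
  structure(
    list(
      probability = out,
      n_subjects = length(binaries),
      contributing_ids = ids %||% paste0("subject_", seq_along(binaries))
    ),
    class = "overlap_map"
  )
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf(
    "<overlap_map> %d subjects, max overlap %.3f, %d voxel(s) with any overlap\n",
    x$n_subjects, max(x$probability$data), sum(x$probability$data > 0)
  ))
  invisible(x)
}

#' Consensus atrophy map at an overlap threshold
#'
#' Retains the voxels atrophic in at least `fraction` of subjects
#' (inclusive bound, so a voxel present in exactly 75% of subjects survives
#' a 0.75 threshold). `fraction = 1` gives the intersection of all subject
#' maps.
#'
#' @param overlap an `overlap_map`.
#' @param fraction overlap threshold in `(0, 1]`, e.g. 0.75 or 0.90.
#' @return A `binary_map` of the consensus voxels.
#' @export
threshold_overlap <- function(overlap, fraction) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  out <- overlap$probability
  out$data <- array(as.numeric(overlap$probability$data >= fraction),
                    dim(out$data))
  structure(
    list(data = out, threshold_p = NA_real_, direction = "consensus",
         overlap_fraction = fraction),
    class = "binary_map"
  )
}

#' Region mask
#'
#' @param name region label (e.g. `"caudate+putamen"`).
#' @param data a binary [volume_image()] (values 0/1).
#' @return A `region_mask` object.
#' @export
region_mask <- function(name, data) {
  stopifnot(is_volume_image(data))
  vals <- unique(as.vector(data$data))
  if (!all(vals %in% c(0, 1))) {
    abort("a region mask must contain only 0/1 values.")
  }
  structure(list(name = name, data = data), class = "region_mask")
}

#' Union of region masks
#'
#' Supports prevalence of atrophy in "either region A or region B" by
#' passing the voxelwise union.
#'
#' @param ... `region_mask` objects on a common grid.
#' @param name label for the union.
#' @return A `region_mask`.
#' @export
mask_union <- function(..., name = NULL) {
  masks <- list(...)
  stopifnot(length(masks) >= 1)
  vols <- lapply(masks, function(m) m$data)
  check_common_grid(vols, names = vapply(masks, `[[`, character(1), "name"))
  u <- vols[[1]]
  u$data <- array(
    as.numeric(Reduce(`+`, lapply(vols, function(v) v$data)) > 0),
    dim(u$data)
  )
  nm <- name %||% paste(vapply(masks, `[[`, character(1), "name"),
                        collapse = "+")
  region_mask(nm, u)
}

#' Atrophy prevalence within a region mask
#'
#' A subject counts as atrophic in the region when at least `min_voxels`
#' of their binary map fall inside the mask; the prevalence is the
#' percentage of subjects that do.
#'
#' @param binaries list of `binary_map` objects.
#' @param mask a `region_mask`.
#' @param min_voxels minimum suprathreshold voxels inside the mask for a
#'   subject to count (default 1).
#' @return A tibble with `region`, `n_subjects`, `count` and `percent`.
#' @export
region_atrophy_prevalence <- function(binaries, mask, min_voxels = 1L) {
  if (sum(mask$data$data) < 1) abort("the region mask is empty.")
  vols <- lapply(binaries, function(b) b$data)
  check_common_grid(c(list(mask$data), vols),
                    names = c(sprintf("mask '%s'", mask$name),
                              paste0("binary map ", seq_along(vols))))
  inside <- mask$data$data == 1
  hits <- vapply(vols, function(v) sum(v$data[inside]), numeric(1))
  count <- sum(hits >= min_voxels)
  tibble::tibble(
    region = mask$name,
    n_subjects = length(binaries),
    count = as.integer(count),
    percent = 100 * count / length(binaries)
  )
}

#' Count affected voxels in a binary atrophy map
#'
#' @param binary a `binary_map`.
#' @param mask optional `region_mask` restricting the count.
#' @return Integer voxel count.
#' @export
affected_voxel_count <- function(binary, mask = NULL) {
  v <- binary$data$data
  if (!is.null(mask)) {
    check_common_grid(list(binary$data, mask$data),
                      names = c("binary map", sprintf("mask '%s'", mask$name)))
    v <- v * mask$data$data
  }
  as.integer(sum(v))
}
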