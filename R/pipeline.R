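#' Write a run manifest
#'
#' Every pipeline output directory gets exactly one `manifest.json`
#' recording the tool version, timestamp, the effective configuration, MD5
#' digests of the input files and any warnings raised during the run, so a
#' result can always be traced back to its inputs and parameters.
#'
#' @param out_dir output directory.
#' @param config named list of effective parameters.
#' @param inputs character vector of input file paths (hashed).
#' @param warnings character vector of warning messages.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, inputs = character(),
                           warnings = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool_version = as.character(utils::packageVersion("braincase")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_snapshot = config,
    input_hashes = as.list(tools::md5sum(inputs)),
    warnings = as.list(warnings)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the ROI-based single-case branch end to end
#'
#' Reads a long biomarker table and subject metadata, compares the named
#' subject against the control group over a disease panel, and writes the
#' result report (CSV and JSON) plus a run manifest into `out_dir`. On
#' error, partial outputs are removed.
#'
#' @param biomarkers_csv path to a long biomarker CSV
#'   (see [read_biomarker_csv()]).
#' @param meta_csv path to the subject metadata CSV
#'   (see [read_subject_meta()]).
#' @param subject_id the case to analyze (must be present in both files).
#' @param out_dir output directory (created if needed).
#' @param disease `"hd"` selects the built-in HD panel; otherwise supply
#'   `panel`.
#' @param panel optional tibble (`region`, `measure`) overriding the
#'   disease panel.
#' @param age_deviation,tiv_normalize,alpha,tails,session passed to
#'   [compare_roi_panel()].
#' @return The `case_panel` object, invisibly.
#' @export
run_roi_branch <- function(biomarkers_csv, meta_csv, subject_id, out_dir,
                           disease = "hd", panel = NULL,
                           age_deviation = 10, tiv_normalize = TRUE,
                           alpha = 0.05, tails = "two", session = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, sprintf("%s_roi_report.csv", subject_id))
  json_path <- file.path(out_dir, sprintf("%s_roi_report.json", subject_id))
  warns <- character()

  run <- function() {
    records <- read_biomarker_csv(biomarkers_csv)
    meta <- read_subject_meta(meta_csv)
    if (!subject_id %in% meta$subject_id) {
      abort(sprintf("subject '%s' not found in '%s'.", subject_id, meta_csv))
    }
    if (is.null(panel)) {
      if (!identical(disease, "hd")) {
        abort(sprintf(
          "no built-in panel for disease '%s'; pass `panel` explicitly.",
          disease
        ))
      }
      panel <- hd_panel()
    }
    subject_age <- meta$age[meta$subject_id == subject_id][1]
    ctrl_ids <- meta$subject_id[meta$group == "control"]
    cmp <- compare_roi_panel(
      subject_records = records[records$subject_id == subject_id, ],
      control_records = records[records$subject_id %in% ctrl_ids, ],
      controls_meta = meta[meta$group == "control", ],
      panel = panel, subject_age = subject_age,
      age_deviation = age_deviation, tiv_normalize = tiv_normalize,
      alpha = alpha, tails = tails, session = session
    )
    td <- tidy(cmp)
    write_report(td, csv_path, "csv")
    write_report(td, json_path, "json")
    write_manifest(
      out_dir,
      config = list(
        branch = "roi", subject_id = subject_id, disease = disease,
        age_deviation = age_deviation, tiv_normalize = tiv_normalize,
        alpha = alpha, tails = tails, session = session,
        n_panel = nrow(panel)
      ),
      inputs = c(biomarkers_csv, meta_csv),
      warnings = warns
    )
    cmp
  }

  res <- tryCatch(
    withCallingHandlers(run(), warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }),
    error = function(e) {
      # remove partial outputs so a failed run leaves nothing behind
      unlink(c(csv_path, json_path, file.path(out_dir, "manifest.json")))
      abort(conditionMessage(e), parent = e)
    }
  )
  invisible(res)
}

#' Run the voxel-wise whole-brain branch end to end
#'
#' Smooths, tests the case image voxel-wise against the control stack,
#' thresholds, and writes the t map, p map, binary atrophy map, a JSON
#' sidecar with the test parameters, and a run manifest.
#'
#' @param subject_nii path to the case's gray-matter NIfTI.
#' @param control_niis character vector of control NIfTI paths (>= 2).
#' @param out_dir output directory.
#' @param fwhm_mm,tails,p_threshold,gm_floor,sd_floor analysis parameters
#'   (see [voxelwise_single_case()] and [threshold_binarize()]).
#' @return A list with the `stat_map` and `binary_map`, invisibly.
#' @export
run_vbm_branch <- function(subject_nii, control_niis, out_dir,
                           fwhm_mm = 8, tails = "less", p_threshold = 0.005,
                           gm_floor = 0.1, sd_floor = 1e-6) {
  if (length(control_niis) < 2) {
    abort("at least 2 control images are required.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subject <- read_volume(subject_nii)
  controls <- lapply(control_niis, read_volume)
  stat <- voxelwise_single_case(
    subject, controls, tails = tails, fwhm_mm = fwhm_mm,
    gm_floor = gm_floor, sd_floor = sd_floor
  )
  binary <- threshold_binarize(stat, p_threshold = p_threshold)

  desc <- sprintf("single-case t, df=%d, fwhm=%gmm, tails=%s",
                  stat$df, fwhm_mm, tails)
  write_volume(stat$t, file.path(out_dir, "tmap.nii.gz"), description = desc)
  write_volume(stat$p, file.path(out_dir, "pmap.nii.gz"), description = desc)
  write_volume(binary$data, file.path(out_dir, "binary.nii.gz"),
               description = sprintf("%s, p<%g", desc, p_threshold))
  write_volume(stat$mask, file.path(out_dir, "mask.nii.gz"))
  jsonlite::write_json(
    list(
      df = stat$df, n_controls = stat$n_controls, fwhm_mm = fwhm_mm,
      tails = tails, p_threshold = p_threshold, gm_floor = gm_floor,
      sd_floor = sd_floor,
      n_mask_voxels = sum(stat$mask$data),
      n_suprathreshold = affected_voxel_count(binary)
    ),
    file.path(out_dir, "vbm_parameters.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_manifest(
    out_dir,
    config = list(
      branch = "vbm", fwhm_mm = fwhm_mm, tails = tails,
      p_threshold = p_threshold, gm_floor = gm_floor, sd_floor = sd_floor
    ),
    inputs = c(subject_nii, control_niis)
  )
  invisible(list(stat = stat, binary = binary))
}
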