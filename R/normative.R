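#' Select the age-matched control window
#'
#' Restricts the control sample to subjects whose age lies within
#' `subject_age` +/- `deviation` years (closed interval), so that the case
#' is only compared to the controls closest in age. The default deviation
#' of 10 years reflects common practice for normative single-case
#' comparison of structural biomarkers.
#'
#' @param controls tibble of control metadata (needs `subject_id`, `age`).
#' @param subject_age the case's age in years.
#' @param deviation half-width of the age window in years (> 0).
#' @return The retained rows of `controls`, order preserved. Warns when
#'   fewer than 5 controls survive; errors when none do.
#' @export
select_age_window <- function(controls, subject_age, deviation = 10) {
  if (!is.finite(deviation) || deviation <= 0) {
    abort("`deviation` must be a positive number of years.")
  }
  keep <- abs(controls$age - subject_age) <= deviation
  out <- controls[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf(
      "no control lies within %.3g years of age %.3g; widen `deviation`.",
      deviation, subject_age
    ))
  }
  if (nrow(out) < 5) {
    warn(sprintf(
      "only %d control(s) within the age window [%.3g, %.3g]; normative estimates will be unstable.",
      nrow(out), subject_age - deviation, subject_age + deviation
    ))
  }
  out
}

#' Normalize volumetric biomarkers by total intracranial volume
#'
#' Divides volume and surface-area records by each subject's estimated
#' total intracranial volume (TIV), turning them into dimensionless
#' head-size-adjusted proportions. Thickness and curvature records pass
#' through unchanged, as do the TIV records themselves. Records that are
#' already normalized raise an error rather than being divided twice.
#'
#' @param records biomarker record tibble.
#' @param tiv either a named numeric vector (`subject_id` -> TIV in mm^3)
#'   or `NULL`, in which case TIV is taken from each subject's own
#'   `etiv_mm3` record in `records`.
#' @return The record tibble with TIV-scaled measures divided and
#'   `normalized` set accordingly.
#' @export
normalize_tiv <- function(records, tiv = NULL) {
  scaled <- records$measure %in% TIV_SCALED_MEASURES &
    records$measure != "etiv_mm3"
  if (any(records$normalized[scaled])) {
    abort("some records are already TIV-normalized; refusing to divide twice.")
  }
  if (is.null(tiv)) {
    etiv <- records[records$measure == "etiv_mm3", , drop = FALSE]
    tiv <- setNames(etiv$value, etiv$subject_id)
    tiv <- tiv[!duplicated(names(tiv))]
  } else if (is.data.frame(tiv)) {
    tiv <- setNames(tiv$etiv_mm3, tiv$subject_id)
  }
  need <- unique(records$subject_id[scaled])
  miss <- setdiff(need, names(tiv))
  if (length(miss) > 0) {
    abort(sprintf(
      "no TIV available for subject(s): %s", paste(miss, collapse = ", ")
    ))
  }
  bad <- names(tiv)[!is.finite(tiv) | tiv <= 0]
  bad <- intersect(bad, need)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive TIV for subject(s): %s", paste(bad, collapse = ", ")
    ))
  }
  records$value[scaled] <- records$value[scaled] /
    unname(tiv[records$subject_id[scaled]])
  records$normalized[scaled] <- TRUE
  records
}

#' Build the normative cohort for one biomarker
#'
#' Collects the retained controls' values for a (region, measure) pair and
#' computes the normative mean and sample standard deviation (n - 1
#' denominator). Controls lacking the biomarker are excluded with a
#' message; fewer than two usable controls is an error because the SD is
#' undefined.
#'
#' @param control_records biomarker record tibble for the controls.
#' @param retained_controls metadata tibble of the age-windowed controls
#'   (needs `subject_id`, `age`).
#' @param region,measure the biomarker key.
#' @param session session index to use (baseline = 1).
#' @return A `normative_cohort` object: values, ids, `n`, `mean`, `sd`,
#'   the realized `age_window`, `normalized` flag and a `degenerate` flag
#'   (`sd == 0`).
#' @export
build_cohort <- function(control_records, retained_controls, region, measure,
                         session = 1L) {
  rec <- control_records[
    control_records$region == region &
      control_records$measure == measure &
      control_records$session == session &
      control_records$subject_id %in% retained_controls$subject_id,
    , drop = FALSE
  ]
  missing_ids <- setdiff(retained_controls$subject_id, rec$subject_id)
  if (length(missing_ids) > 0) {
    inform(sprintf(
      "%d control(s) lack %s/%s at session %d and were excluded: %s",
      length(missing_ids), region, measure, session,
      paste(head(missing_ids, 5), collapse = ", ")
    ))
  }
  if (nrow(rec) < 2) {
    abort(sprintf(
      "fewer than 2 controls carry %s/%s at session %d; the normative SD is undefined.",
      region, measure, session
    ))
  }
  values <- rec$value
  ages <- retained_controls$age[match(rec$subject_id, retained_controls$subject_id)]
  s <- sd(values)
  structure(
    list(
      region = region, measure = measure,
      values = values, control_ids = rec$subject_id,
      n = length(values), mean = mean(values), sd = s,
      age_window = range(ages),
      normalized = any(rec$normalized),
      degenerate = (s == 0)
    ),
    class = "normative_cohort"
  )
}

#' @export
print.normative_cohort <- function(x, ...) {
  cat(sprintf(
    "<normative_cohort> %s/%s: n=%d, mean=%.6g, sd=%.6g, ages [%.1f, %.1f]%s\n",
    x$region, x$measure, x$n, x$mean, x$sd,
    x$age_window[1], x$age_window[2],
    if (x$degenerate) " [degenerate: sd = 0]" else ""
  ))
  invisible(x)
}
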