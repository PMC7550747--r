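#' Read a subcortical segmentation statistics table (aseg.stats dialect)
#'
#' Parses the text table written by surface-based segmentation pipelines:
#' comment lines starting with `#`, among them `# Measure` summary lines
#' (estimated total intracranial volume, total gray/white matter,
#' ventricles), followed by a whitespace-delimited per-structure table whose
#' columns include `SegId`, `Volume_mm3` and `StructName`.
#'
#' Recognized `# Measure` names are mapped to canonical measures:
#' `EstimatedTotalIntraCranialVol` to `etiv_mm3`, `TotalGrayVol` to
#' `gm_total_mm3`, `CerebralWhiteMatterVol` to `wm_total_mm3`,
#' `VentricleChoroidVol` to `ventricles_mm3`. Unrecognized Measure lines are
#' ignored. Region names are kept verbatim (e.g. `"Left-Caudate"`).
#'
#' @param path path to the stats file.
#' @param subject_id subject identifier to stamp on every record.
#' @param session acquisition session index (1 = baseline).
#' @return A tibble of biomarker records with columns `subject_id`,
#'   `session`, `region`, `measure`, `value`, `normalized` (always `FALSE`
#'   here).
#' @export
read_aseg_stats <- function(path, subject_id, session = 1L) {
  lines <- readLines(path, warn = FALSE)
  session <- as.integer(session)

  meas <- parse_measure_lines(lines)
  tab <- parse_stats_table(
    lines,
    required = c("SegId", "Volume_mm3", "StructName"),
    path = path
  )

  region_records <- if (nrow(tab) > 0) {
    tibble::tibble(
      subject_id = subject_id, session = session,
      region = tab$StructName,
      measure = "volume_mm3",
      value = as_numeric_checked(tab$Volume_mm3, tab$.line, "Volume_mm3", path),
      normalized = FALSE
    )
  } else {
    empty_biomarker_table()
  }

  measure_records <- if (nrow(meas) > 0) {
    tibble::tibble(
      subject_id = subject_id, session = session,
      region = "Global", measure = meas$measure, value = meas$value,
      normalized = FALSE
    )
  } else {
    empty_biomarker_table()
  }

  out <- dplyr::bind_rows(measure_records, region_records)
  check_record_uniqueness(out, path)
  out
}

#' Read a cortical parcellation statistics table (aparc.stats dialect)
#'
#' Each table row yields four records — surface area, gray-matter volume,
#' average thickness and mean curvature — for the region named
#' `<hemisphere>-<StructName>` (e.g. `"lh-precentral"`).
#'
#' @inheritParams read_aseg_stats
#' @param hemisphere `"lh"` or `"rh"`. If the file's own `# hemi` comment
#'   disagrees, a warning is emitted and the argument wins.
#' @return A tibble of biomarker records (four per table row).
#' @export
read_aparc_stats <- function(path, hemisphere = c("lh", "rh"), subject_id,
                             session = 1L) {
  hemisphere <- match.arg(hemisphere)
  session <- as.integer(session)
  lines <- readLines(path, warn = FALSE)

  hemi_line <- grep("^#\\s*hemi\\s+", lines, value = TRUE)
  if (length(hemi_line) > 0) {
    file_hemi <- sub("^#\\s*hemi\\s+", "", hemi_line[1])
    file_hemi <- trimws(file_hemi)
    if (nzchar(file_hemi) && file_hemi != hemisphere) {
      warn(sprintf(
        "'%s' declares hemisphere '%s' but '%s' was requested; using '%s'.",
        path, file_hemi, hemisphere, hemisphere
      ))
    }
  }

  tab <- parse_stats_table(
    lines,
    required = c("StructName", "SurfArea", "GrayVol", "ThickAvg", "MeanCurv"),
    path = path
  )
  if (anyDuplicated(tab$StructName)) {
    dup <- unique(tab$StructName[duplicated(tab$StructName)])
    abort(sprintf(
      "duplicated StructName row(s) in '%s': %s", path,
      paste(dup, collapse = ", ")
    ))
  }
  if (nrow(tab) == 0) {
    return(empty_biomarker_table())
  }

  region <- paste0(hemisphere, "-", tab$StructName)
  num <- function(col) as_numeric_checked(tab[[col]], tab$.line, col, path)
  out <- tibble::tibble(
    subject_id = subject_id, session = session,
    region = rep(region, times = 4L),
    measure = rep(
      c("surface_area_mm2", "volume_mm3", "thickness_mm", "mean_curvature"),
      each = nrow(tab)
    ),
    value = c(num("SurfArea"), num("GrayVol"), num("ThickAvg"),
              num("MeanCurv")),
    normalized = FALSE
  )
  check_record_uniqueness(out, path)
  out
}

#' Read and write long-format biomarker tables
#'
#' The long CSV format (`subject_id,session,region,measure,value`) is the
#' segmentation-independent ingestion path: any tool that can emit one value
#' per subject/region/measure can feed the normative comparison. Rows whose
#' value is missing are skipped with a warning that reports the count.
#'
#' @param path CSV path.
#' @return `read_biomarker_csv()`: a tibble of biomarker records.
#' @export
read_biomarker_csv <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      session = readr::col_integer(),
      region = readr::col_character(),
      measure = readr::col_character(),
      value = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  need <- c("subject_id", "session", "region", "measure", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf(
      "'%s' is missing required column(s): %s", path,
      paste(miss, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(df$measure), BIOMARKER_MEASURES)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown measure name(s) %s; allowed measures are: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(BIOMARKER_MEASURES, collapse = ", ")
    ))
  }
  n_na <- sum(is.na(df$value))
  if (n_na > 0) {
    warn(sprintf("skipped %d record(s) with missing value in '%s'.", n_na, path))
    df <- df[!is.na(df$value), , drop = FALSE]
  }
  if (!"normalized" %in% names(df)) df$normalized <- FALSE
  out <- tibble::as_tibble(df[, c(need, "normalized")])
  check_record_uniqueness(out, path)
  out
}

#' @rdname read_biomarker_csv
#' @param records a biomarker record tibble.
#' @return `write_biomarker_csv()`: `path`, invisibly.
#' @export
write_biomarker_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read subject metadata
#'
#' Expects columns `subject_id`, `group` (`control`/`patient`), `age`
#' (years) and optionally `sex`, `cag` (CAG repeat length) plus any clinical
#' score columns, which are carried through untouched.
#'
#' @param path CSV path.
#' @return A tibble, one row per subject (or per subject/session if a
#'   `session` column is present).
#' @export
read_subject_meta <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_guess()
  ))
  need <- c("subject_id", "group", "age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf(
      "'%s' is missing required metadata column(s): %s", path,
      paste(miss, collapse = ", ")
    ))
  }
  bad_grp <- setdiff(unique(df$group), c("control", "patient"))
  if (length(bad_grp) > 0) {
    abort(sprintf(
      "unknown group value(s): %s (expected 'control' or 'patient')",
      paste(sQuote(bad_grp), collapse = ", ")
    ))
  }
  if (any(!is.finite(df$age) | df$age <= 0)) {
    abort(sprintf("'%s' contains non-positive or missing ages.", path))
  }
  tibble::as_tibble(df)
}

# ---- internal parsing helpers ------------------------------------------

MEASURE_LINE_MAP <- c(
  EstimatedTotalIntraCranialVol = "etiv_mm3",
  TotalGrayVol = "gm_total_mm3",
  CerebralWhiteMatterVol = "wm_total_mm3",
  VentricleChoroidVol = "ventricles_mm3"
)

parse_measure_lines <- function(lines) {
  ml <- grep("^#\\s*Measure\\s+", lines, value = TRUE)
  out <- list()
  for (l in ml) {
    body <- sub("^#\\s*Measure\\s+", "", l)
    parts <- trimws(strsplit(body, ",")[[1]])
    # name, short, description, value, unit — but some dialect versions
    # swap name/short (e.g. "TotalGray, TotalGrayVol"), so match either
    if (length(parts) < 4) next
    name <- intersect(parts[1:2], names(MEASURE_LINE_MAP))[1]
    if (is.na(name)) next  # unrecognized Measure line: ignore
    value <- suppressWarnings(as.numeric(parts[length(parts) - 1L]))
    if (is.na(value)) next
    out[[length(out) + 1L]] <- list(
      measure = unname(MEASURE_LINE_MAP[name]), value = value
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(measure = character(), value = numeric()))
  }
  tibble::tibble(
    measure = vapply(out, `[[`, character(1), "measure"),
    value = vapply(out, `[[`, numeric(1), "value")
  )
}

parse_stats_table <- function(lines, required, path) {
  ch <- grep("^#\\s*ColHeaders\\s+", lines)
  if (length(ch) > 0) {
    headers <- strsplit(
      trimws(sub("^#\\s*ColHeaders\\s+", "", lines[ch[1]])), "\\s+"
    )[[1]]
  } else {
    # fall back: first non-comment line is the header row
    body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
    if (length(body_idx) == 0) {
      abort(sprintf(
        "'%s' has no table header; required column(s): %s", path,
        paste(required, collapse = ", ")
      ))
    }
    headers <- strsplit(trimws(lines[body_idx[1]]), "\\s+")[[1]]
    lines[body_idx[1]] <- "#"  # consume it
  }
  miss <- setdiff(required, headers)
  if (length(miss) > 0) {
    abort(sprintf(
      "'%s' table header is missing required column(s): %s", path,
      paste(miss, collapse = ", ")
    ))
  }
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- lapply(body_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != length(headers)) {
      abort(sprintf(
        "line %d of '%s' has %d fields but the header declares %d columns.",
        i, path, length(fields), length(headers)
      ))
    }
    fields
  })
  if (length(rows) == 0) {
    tab <- as.data.frame(
      matrix(character(), 0, length(headers), dimnames = list(NULL, headers)),
      stringsAsFactors = FALSE
    )
    tab$.line <- integer()
    return(tab)
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- headers
  tab$.line <- body_idx
  tab
}

as_numeric_checked <- function(x, line, column, path) {
  val <- suppressWarnings(as.numeric(x))
  if (any(is.na(val))) {
    i <- which(is.na(val))[1]
    abort(sprintf(
      "non-numeric value '%s' in column %s at line %d of '%s'.",
      x[i], column, line[i], path
    ))
  }
  val
}

empty_biomarker_table <- function() {
  tibble::tibble(
    subject_id = character(), session = integer(), region = character(),
    measure = character(), value = numeric(), normalized = logical()
  )
}

check_record_uniqueness <- function(records, path = "<records>") {
  key <- paste(records$subject_id, records$session, records$region,
               records$measure, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "duplicate (subject, session, region, measure) record(s) in '%s', e.g. %s/%s.",
      path, dup$region[1], dup$measure[1]
    ))
  }
  invisible(records)
}
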