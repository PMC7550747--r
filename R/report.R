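#' Write and read single-case comparison reports
#'
#' Serializes a tidied single-case result table (see [compare_roi_panel()]
#' and [tidy()]) to CSV or JSON. Column order and names are stable:
#' `region, measure, n_controls, control_mean, control_sd, z, t, df, p,
#' p_adj, significant, direction`. Numeric fields keep full double
#' precision (at least 10 significant digits) so reports round-trip.
#'
#' @param results a tibble of single-case results, as returned by
#'   `tidy(compare_roi_panel(...))`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c(
    "region", "measure", "n_controls", "control_mean", "control_sd",
    "z", "t", "df", "p", "p_adj", "significant", "direction"
  )
  miss <- setdiff(cols, names(results))
  if (length(miss) > 0) {
    abort(sprintf(
      "results table is missing column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  out <- results[, cols, drop = FALSE]
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(out, path, digits = NA, dataframe = "rows",
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()`: the result tibble.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(
      region = readr::col_character(),
      measure = readr::col_character(),
      n_controls = readr::col_integer(),
      df = readr::col_integer(),
      significant = readr::col_logical(),
      direction = readr::col_character(),
      .default = readr::col_double()
    ))
  } else {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) {
      df <- tibble::tibble(
        region = character(), measure = character(),
        n_controls = integer(), control_mean = numeric(),
        control_sd = numeric(), z = numeric(), t = numeric(),
        df = integer(), p = numeric(), p_adj = numeric(),
        significant = logical(), direction = character()
      )
    }
    df$n_controls <- as.integer(df$n_controls)
    df$df <- as.integer(df$df)
  }
  tibble::as_tibble(df)
}
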