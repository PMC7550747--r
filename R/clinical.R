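#' Huntington's disease burden score
#'
#' The CAG-and-age progression index `Age * (CAG - 35.5)`. Negative values
#' (CAG below 35.5, i.e. below the pathological expansion range) are
#' allowed but flagged with a warning.
#'
#' @param age age in years (> 0), vectorized.
#' @param cag CAG repeat length, vectorized; missing values are an error.
#' @return Numeric disease-burden score(s).
#' @examples
#' disease_burden(40, 43.5)  # 320
#' @export
disease_burden <- function(age, cag) {
  if (any(!is.finite(age) | age <= 0)) {
    abort("`age` must be positive and finite.")
  }
  if (any(is.na(cag))) {
    abort("`cag` is missing for some subject(s); the disease burden needs the CAG repeat length.")
  }
  burden <- age * (cag - 35.5)
  if (any(burden < 0)) {
    warn("negative disease burden (CAG < 35.5) for some subject(s).")
  }
  burden
}

#' Pearson correlation with a two-tailed p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @return A list with `r`, `p`, `n` and `df`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("at least 3 pairs are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in `x` or `y`; the correlation is undefined.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = length(x) - 2L)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` with the linear effect of `z` removed:
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' equal to the Pearson correlation of the residuals from regressing `x`
#' and `y` on `z`. The p-value uses `df = n - 3`.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4).
#' @return A list with `r`, `p`, `n` and `df`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    abort("`x`, `y` and `z` must have equal length.")
  }
  if (n < 4) abort("at least 4 observations are required (df = n - 3).")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    abort("zero variance among the inputs; the partial correlation is undefined.")
  }
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    abort("`z` is collinear with `x` or `y`; the partial correlation is degenerate.")
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  df <- n - 3L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df)
  list(r = r, p = p, n = n, df = df)
}

#' Annualized rate of change of a longitudinal biomarker
#'
#' For two sessions this is the value difference divided by the elapsed
#' time in years (`interval_months / 12`); with more sessions it is the
#' ordinary least-squares slope of value on time-in-years, which reduces
#' to the two-point rate for collinear or two-point input.
#'
#' @param series a tibble/data.frame with columns `interval_months`
#'   (time from baseline, strictly increasing, first value 0) and `value`.
#' @return The rate in value units per year.
#' @export
annualized_rate <- function(series) {
  t_m <- series$interval_months
  v <- series$value
  if (length(t_m) < 2) abort("at least 2 sessions are required.")
  if (any(diff(t_m) <= 0)) {
    abort("session intervals must be strictly increasing.")
  }
  if (max(t_m) - min(t_m) <= 0) abort("zero elapsed time between sessions.")
  years <- t_m / 12
  if (length(t_m) == 2L) {
    return((v[2] - v[1]) / (years[2] - years[1]))
  }
  unname(coef(lm(v ~ years))[2])
}

#' Annualized rates for a long biomarker table
#'
#' Convenience wrapper computing [annualized_rate()] per subject and
#' biomarker from a long table.
#'
#' @param data tibble with columns `subject_id`, `region`, `measure`,
#'   `interval_months`, `value`.
#' @return A tibble with one row per subject/region/measure and a
#'   `rate_per_year` column.
#' @export
annualized_rates <- function(data) {
  data |>
    dplyr::group_by(.data$subject_id, .data$region, .data$measure) |>
    dplyr::arrange(.data$interval_months, .by_group = TRUE) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      rate_per_year = annualized_rate(
        data.frame(interval_months = interval_months, value = value)
      ),
      .groups = "drop"
    )
}

#' Compare atrophy rates between patients and controls
#'
#' Two-sample Student t-test (pooled variance by default) on per-subject
#' annualized rates; an unequal-variance (Welch) variant is available.
#'
#' @param patient_rates,control_rates numeric vectors of per-subject rates
#'   (each n >= 2).
#' @param var_equal pooled-variance test when `TRUE` (default).
#' @return A list with `t`, `df`, `p`, group means and the variant used.
#' @export
group_rate_test <- function(patient_rates, control_rates, var_equal = TRUE) {
  if (length(patient_rates) < 2 || length(control_rates) < 2) {
    abort("each group needs at least 2 subjects.")
  }
  if (sd(c(patient_rates - mean(patient_rates),
           control_rates - mean(control_rates))) == 0) {
    abort("zero pooled variance; the rate comparison is undefined.")
  }
  tt <- t.test(patient_rates, control_rates, var.equal = var_equal)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_patients = mean(patient_rates), mean_controls = mean(control_rates),
    variant = if (var_equal) "pooled" else "welch"
  )
}
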