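#' Single-case z-score
#'
#' Standardizes one subject's biomarker value against the normative cohort:
#' `(x_star - mean) / sd`. The z-score treats the normative mean and SD as
#' known population values, which is anti-conservative for small control
#' samples — see [crawford_howell_t()] for the calibrated alternative.
#'
#' @param x_star the case's value.
#' @param cohort a `normative_cohort` (or any list with `mean` and `sd`).
#' @return The z-score (numeric scalar, vectorized over `x_star`).
#' @export
z_score <- function(x_star, cohort) {
  if (!is.finite(cohort$sd) || cohort$sd <= 0) {
    abort("degenerate normative cohort: sd must be > 0 for a z-score.")
  }
  (x_star - cohort$mean) / cohort$sd
}

#' Crawford-Howell modified t-test for a single case
#'
#' Tests whether one observation could have been drawn from a small
#' normative sample, treating the control mean and SD as estimates rather
#' than population values:
#' \deqn{t = \frac{x^* - \bar{x}}{s \sqrt{(n+1)/n}}, \quad df = n - 1.}
#' Unlike the naive z-score, this statistic follows an exact Student t
#' distribution under the null for any control sample size `n >= 2`, so
#' its p-values stay calibrated even for very small cohorts.
#'
#' @inheritParams z_score
#' @param tails `"two"` (default), `"less"` (case below the norm) or
#'   `"greater"`.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' cohort <- list(mean = 12, sd = 2, n = 3)
#' crawford_howell_t(8, cohort)  # t = -1.73, df = 2
#' @export
crawford_howell_t <- function(x_star, cohort, tails = c("two", "less", "greater")) {
  tails <- match.arg(tails)
  n <- cohort$n
  if (is.null(n) || n < 2) {
    abort("Crawford-Howell t needs a normative cohort of size n >= 2.")
  }
  if (!is.finite(cohort$sd) || cohort$sd <= 0) {
    abort("degenerate normative cohort: sd must be > 0.")
  }
  t_stat <- (x_star - cohort$mean) / (cohort$sd * sqrt((n + 1) / n))
  df <- n - 1L
  p <- switch(tails,
    two = 2 * pt(-abs(t_stat), df),
    less = pt(t_stat, df),
    greater = pt(t_stat, df, lower.tail = FALSE)
  )
  list(t = t_stat, df = as.integer(df), p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment over a panel of p-values: adjusted values are
#' `p_(i) * m / i` made monotone from the largest rank down and capped at
#' 1; a hypothesis is rejected when its adjusted p is strictly below `q`.
#' Tied p-values receive identical adjusted values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q the FDR level (default 0.05).
#' @return A list with `p_adj` (same order as input) and `rejected`
#'   (logical).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) > 0 &&
      (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))) {
    abort("all p-values must lie in [0, 1].")
  }
  p_adj <- p.adjust(p_values, method = "BH")
  list(p_adj = p_adj, rejected = p_adj < q)
}

#' Compare one subject against the normative cohort over a region panel
#'
#' The ROI-based branch of the single-subject comparison. For every
#' biomarker key in `panel` the pipeline is: select the age-matched
#' controls, optionally divide head-size-dependent measures by TIV, build
#' the normative cohort, compute the z-score and the Crawford-Howell t,
#' then apply one Benjamini-Hochberg correction across the whole panel
#' (`m` = panel size). The significance decision is made on the FDR-adjusted
#' p of the modified t (strictly below `alpha`); both z and t are always
#' reported.
#'
#' @param subject_records biomarker tibble for the case (one subject).
#' @param control_records biomarker tibble for the controls.
#' @param controls_meta metadata tibble for the controls (`subject_id`,
#'   `age`, ...).
#' @param panel tibble with columns `region` and `measure` — the biomarker
#'   keys to test (see [hd_panel()]).
#' @param subject_age the case's age in years.
#' @param age_deviation half-width of the age window (years).
#' @param tiv_normalize divide TIV-scaled measures by each subject's
#'   estimated total intracranial volume before comparison.
#' @param alpha significance level applied to the FDR-adjusted p.
#' @param tails tail choice passed to [crawford_howell_t()].
#' @param session session index (baseline = 1).
#' @return A `case_panel` object; use [tidy()] for the per-region result
#'   tibble and [glance()] for a one-row summary.
#' @export
compare_roi_panel <- function(subject_records, control_records, controls_meta,
                              panel, subject_age,
                              age_deviation = 10, tiv_normalize = TRUE,
                              alpha = 0.05, tails = "two", session = 1L) {
  stopifnot(all(c("region", "measure") %in% names(panel)))
  session <- as.integer(session)

  subj <- subject_records[subject_records$session == session, , drop = FALSE]
  have <- paste(subj$region, subj$measure)
  want <- paste(panel$region, panel$measure)
  missing_keys <- setdiff(want, have)
  if (length(missing_keys) > 0) {
    abort(sprintf(
      "panel key(s) missing for the subject: %s",
      paste(missing_keys, collapse = "; ")
    ))
  }

  retained <- select_age_window(controls_meta, subject_age, age_deviation)

  if (isTRUE(tiv_normalize)) {
    subj <- normalize_tiv(subj)
    ctrl <- normalize_tiv(
      control_records[control_records$session == session, , drop = FALSE]
    )
  } else {
    ctrl <- control_records[control_records$session == session, , drop = FALSE]
  }

  rows <- purrr::pmap(panel[, c("region", "measure")], function(region, measure) {
    cohort <- build_cohort(ctrl, retained, region, measure, session = session)
    x_star <- subj$value[subj$region == region & subj$measure == measure][1]
    z <- z_score(x_star, cohort)
    ch <- crawford_howell_t(x_star, cohort, tails = tails)
    tibble::tibble(
      region = region, measure = measure, x_star = x_star,
      n_controls = cohort$n, control_mean = cohort$mean,
      control_sd = cohort$sd, z = z, t = ch$t, df = ch$df, p = ch$p
    )
  })
  res <- dplyr::bind_rows(rows)

  fdr <- bh_fdr(res$p, q = alpha)
  res$p_adj <- fdr$p_adj
  res$significant <- fdr$rejected
  res$direction <- dplyr::case_when(
    res$t == 0 ~ "none",
    res$x_star < res$control_mean ~ "below",
    TRUE ~ "above"
  )

  structure(
    list(
      results = res,
      subject_id = subject_records$subject_id[1],
      subject_age = subject_age,
      age_deviation = age_deviation,
      n_retained_controls = nrow(retained),
      tiv_normalize = isTRUE(tiv_normalize),
      alpha = alpha, tails = tails, session = session
    ),
    class = "case_panel"
  )
}

#' @export
print.case_panel <- function(x, ...) {
  cat(sprintf(
    "<case_panel> subject %s (age %.1f) vs %d controls, %d biomarker(s), %d significant at FDR alpha = %g\n",
    x$subject_id %||% "?", x$subject_age, x$n_retained_controls,
    nrow(x$results), sum(x$results$significant), x$alpha
  ))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy a single-case panel comparison
#'
#' @param x a `case_panel` from [compare_roi_panel()].
#' @param ... unused.
#' @return A tibble with one row per panel biomarker: region, measure,
#'   cohort size and moments, z, t, df, raw and FDR-adjusted p,
#'   significance flag and direction of deviation.
#' @method tidy case_panel
#' @export
tidy.case_panel <- function(x, ...) {
  x$results[, c(
    "region", "measure", "n_controls", "control_mean", "control_sd",
    "z", "t", "df", "p", "p_adj", "significant", "direction"
  )]
}

#' @rdname tidy.case_panel
#' @method glance case_panel
#' @export
glance.case_panel <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id %||% NA_character_,
    subject_age = x$subject_age,
    n_controls = x$n_retained_controls,
    n_panel = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_below = sum(x$results$significant & x$results$direction == "below"),
    n_above = sum(x$results$significant & x$results$direction == "above"),
    alpha = x$alpha,
    tails = x$tails,
    tiv_normalized = x$tiv_normalize
  )
}

#' Plot a single-case panel comparison
#'
#' Deviation plot: one bar per biomarker showing the case's z-score, filled
#' by FDR-level significance of the Crawford-Howell test.
#'
#' @param object a `case_panel`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot case_panel
#' @export
autoplot.case_panel <- function(object, ...) {
  d <- tidy(object)
  d$label <- paste(d$region, d$measure, sep = "\n")
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, .data$z), y = .data$z,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "z-score vs normative cohort",
      fill = sprintf("FDR p-adj < %g", object$alpha),
      title = sprintf("Single-case deviation profile: %s",
                      object$subject_id %||% "")
    ) +
    ggplot2::theme_minimal()
}
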