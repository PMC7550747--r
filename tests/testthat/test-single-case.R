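test_that("z-scores standardize against the cohort moments", {
  coh <- mini_cohort(c(10, 12, 14))
  expect_equal(z_score(12, coh), 0)
  expect_equal(z_score(8, coh), -2)
  coh0 <- mini_cohort(c(7, 7, 7))
  expect_error(z_score(8, coh0), "degenerate")
})

test_that("the modified t matches its closed form and the t CDF oracle", {
  coh <- mini_cohort(c(10, 12, 14))   # n=3, mean 12, sd 2
  ch <- crawford_howell_t(8, coh)
  expect_equal(ch$t, -4 / (2 * sqrt(4 / 3)), tolerance = 1e-10)
  expect_equal(ch$t, -1.7320508, tolerance = 1e-7)
  expect_equal(ch$df, 2L)
  expect_equal(ch$p, 2 * t_cdf_oracle(ch$t, 2), tolerance = 1e-12)

  # case at the normative mean: t = 0, two-tailed p = 1
  ch0 <- crawford_howell_t(12, coh)
  expect_equal(ch0$t, 0)
  expect_equal(ch0$p, 1)

  # guards
  expect_error(crawford_howell_t(8, mini_cohort(c(7, 7, 7))), "degenerate")
  expect_error(crawford_howell_t(8, list(mean = 0, sd = 1, n = 1)), "n >= 2")
})

test_that("modified t converges to the z statistic for huge cohorts", {
  big <- list(mean = 0, sd = 1, n = 1e6)
  for (x in c(-3.7, -1.2, 0.4, 2.9)) {
    z <- z_score(x, big)
    t_val <- crawford_howell_t(x, big)$t
    expect_equal(t_val, z * sqrt(1e6 / (1e6 + 1)), tolerance = 1e-12)
    expect_lt(abs(t_val - z), 1e-5 * abs(z))
  }
})

test_that("p-values agree with an independent Student-t CDF to 1e-6", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(2:30, 1)
    vals <- rnorm(n, sd = runif(1, 0.5, 5))
    if (sd(vals) == 0) next
    coh <- mini_cohort(vals)
    x <- rnorm(1, coh$mean, 3 * coh$sd)
    ch <- crawford_howell_t(x, coh)
    expect_equal(ch$p, 2 * t_cdf_oracle(-abs(ch$t), n - 1), tolerance = 1e-6)
  }
})

test_that("p never increases as the case moves away from the norm", {
  coh <- mini_cohort(rnorm(10, 100, 15))
  deltas <- seq(0, 5, by = 0.25)
  ps <- vapply(deltas, function(d) {
    crawford_howell_t(coh$mean - d * coh$sd, coh)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  # worked example: uniform ladder collapses to the top value
  ex <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(ex$p_adj, rep(0.04, 4))

  expect_equal(bh_fdr(0.03)$p_adj, 0.03)            # m = 1 identity
  all1 <- bh_fdr(rep(1, 5))
  expect_equal(all1$p_adj, rep(1, 5))
  expect_false(any(all1$rejected))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(202)
  for (rep in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)
    if (rep %% 3 == 0 && m > 2) p[2] <- p[1]        # exercise ties
    if (rep %% 7 == 0) p <- round(p, 1)             # heavy ties
    expect_equal(bh_fdr(p)$p_adj, bh_oracle(p))
  }
})

# --- the assembled ROI panel -------------------------------------------

panel_fixture <- function(seed = 5, effect = NULL, n_controls = 20) {
  panel12 <- default_roi_panel()[1:12, ]
  implants <- NULL
  if (!is.null(effect)) {
    implants <- tibble::tibble(
      subject_id = "pat001", region = "Left-Caudate",
      measure = "volume_mm3", effect_sd = effect
    )
  }
  cfg <- simulation_config(
    seed = seed, n_controls = n_controls, n_patients = 1,
    roi_panel = panel12, implants_roi = implants
  )
  sim <- simulate_cohort(cfg)
  list(sim = sim, panel = panel12[, c("region", "measure")], cfg = cfg)
}

test_that("a strongly atrophic region is flagged below the norm", {
  fx <- panel_fixture(seed = 5, effect = -5)
  meta <- fx$sim$meta
  rec <- fx$sim$records
  cmp <- compare_roi_panel(
    subject_records = rec[rec$subject_id == "pat001", ],
    control_records = rec[rec$subject_id != "pat001", ],
    controls_meta = meta[meta$group == "control", ],
    panel = fx$panel,
    subject_age = meta$age[meta$subject_id == "pat001"],
    age_deviation = 1e6
  )
  td <- tidy(cmp)
  row <- td[td$region == "Left-Caudate", ]
  expect_true(row$significant)
  expect_equal(row$direction, "below")
  expect_lt(row$z, -3)
  expect_true(all(td$p_adj >= td$p - 1e-15))
  expect_lt(abs(row$t), abs(row$z))     # shrinkage toward zero for finite n

  g <- glance(cmp)
  expect_equal(g$n_panel, 12L)
  expect_gte(g$n_significant, 1L)
})

test_that("a panel of size one leaves the p-value unadjusted", {
  fx <- panel_fixture(seed = 9)
  meta <- fx$sim$meta
  rec <- fx$sim$records
  cmp <- compare_roi_panel(
    subject_records = rec[rec$subject_id == "pat001", ],
    control_records = rec[rec$subject_id != "pat001", ],
    controls_meta = meta[meta$group == "control", ],
    panel = fx$panel[1, ],
    subject_age = meta$age[meta$subject_id == "pat001"],
    age_deviation = 1e6
  )
  td <- tidy(cmp)
  expect_equal(td$p_adj, td$p)
})

test_that("panel keys absent for the subject are all named in the error", {
  fx <- panel_fixture(seed = 5)
  meta <- fx$sim$meta
  rec <- fx$sim$records
  bad_panel <- dplyr::bind_rows(
    fx$panel,
    tibble::tibble(region = c("Left-Amygdala", "Right-Amygdala"),
                   measure = "volume_mm3")
  )
  err <- expect_error(
    compare_roi_panel(
      subject_records = rec[rec$subject_id == "pat001", ],
      control_records = rec[rec$subject_id != "pat001", ],
      controls_meta = meta[meta$group == "control", ],
      panel = bad_panel,
      subject_age = meta$age[meta$subject_id == "pat001"],
      age_deviation = 1e6
    ),
    "missing"
  )
  expect_match(conditionMessage(err), "Left-Amygdala")
  expect_match(conditionMessage(err), "Right-Amygdala")
})
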