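test_that("identical seed and config reproduce identical outputs", {
  cfg <- simulation_config(seed = 7, n_controls = 5, n_patients = 3,
                           grid_shape = c(8, 8, 8))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  ia <- simulate_gm_images(cfg)
  ib <- simulate_gm_images(cfg)
  expect_identical(lapply(ia, `[[`, "data"), lapply(ib, `[[`, "data"))
})

test_that("growing the cohort never reshuffles earlier subjects", {
  small <- simulate_cohort(simulation_config(seed = 7, n_controls = 5,
                                             n_patients = 0))
  big <- simulate_cohort(simulation_config(seed = 7, n_controls = 9,
                                           n_patients = 0))
  ids <- small$meta$subject_id
  expect_identical(small$meta, big$meta[big$meta$subject_id %in% ids, ])
  expect_identical(
    as.data.frame(small$records),
    as.data.frame(big$records[big$records$subject_id %in% ids, ])
  )
})

test_that("cohort tables honor the metadata and record invariants", {
  cfg <- simulation_config(seed = 13, n_controls = 10, n_patients = 6)
  sim <- simulate_cohort(cfg)

  expect_equal(sum(sim$meta$group == "control"), 10L)
  expect_equal(sum(sim$meta$group == "patient"), 6L)
  expect_true(all(sim$meta$age >= 25 & sim$meta$age <= 65))
  expect_true(all(is.na(sim$meta$cag[sim$meta$group == "control"])))
  pat_cag <- sim$meta$cag[sim$meta$group == "patient"]
  expect_true(all(pat_cag >= 40 & pat_cag <= 48))

  etiv <- sim$records[sim$records$measure == "etiv_mm3", ]
  expect_equal(nrow(etiv), 16L)
  expect_true(all(etiv$value > 0))
  # generated tables pass the real CSV parser round trip
  f <- tempfile(fileext = ".csv")
  write_biomarker_csv(sim$records, f)
  expect_equal(as.data.frame(read_biomarker_csv(f)),
               as.data.frame(sim$records))
})

test_that("ROI implants shift the expected z by the requested effect", {
  panel1 <- default_roi_panel()[1, ]
  n_pat <- 120
  implants <- tibble::tibble(
    subject_id = sprintf("pat%03d", seq_len(n_pat)),
    region = panel1$region, measure = panel1$measure, effect_sd = -3
  )
  cfg <- simulation_config(seed = 17, n_controls = 200, n_patients = n_pat,
                           roi_panel = panel1, implants_roi = implants,
                           tiv_sd = 0)
  sim <- simulate_cohort(cfg)
  rec <- dplyr::inner_join(sim$records, sim$meta, by = "subject_id")
  rec <- rec[rec$measure == "volume_mm3", ]
  # remove the age trend before standardizing against the controls
  mid <- mean(cfg$age_range)
  rec$detrended <- rec$value - panel1$age_slope * (rec$age - mid)
  ctrl <- rec$detrended[rec$group == "control"]
  pat <- rec$detrended[rec$group == "patient"]
  z_pat <- (pat - mean(ctrl)) / sd(ctrl)
  # mean implanted z is -3 within Monte-Carlo error (~3 SE)
  expect_lt(abs(mean(z_pat) + 3), 3 / sqrt(n_pat) + 0.15)
})

test_that("noise-free images equal the template; implants lower the sphere", {
  cfg0 <- simulation_config(seed = 19, n_controls = 2, n_patients = 0,
                            grid_shape = c(12, 12, 12), image_noise_sd = 0)
  imgs0 <- simulate_gm_images(cfg0)
  templ <- attr(imgs0, "template")
  expect_identical(imgs0$ctrl001$data, templ$data)
  expect_identical(imgs0$ctrl002$data, templ$data)

  cfg <- simulation_config(
    seed = 19, n_controls = 20, n_patients = 1,
    grid_shape = c(16, 16, 16), image_noise_sd = 0.1,
    implants_voxel = tibble::tibble(subject_id = "pat001", cx = 7, cy = 7,
                                    cz = 7, radius = 3, effect_sd = 4)
  )
  imgs <- simulate_gm_images(cfg)
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  sphere <- array((g$x - 7)^2 + (g$y - 7)^2 + (g$z - 7)^2 <= 9, c(16, 16, 16))
  ctrl_mean <- Reduce(`+`, lapply(
    imgs[startsWith(names(imgs), "ctrl")], `[[`, "data"
  )) / 20
  drop <- mean(ctrl_mean[sphere]) - mean(imgs$pat001$data[sphere])
  expect_equal(drop, 4 * 0.1, tolerance = 0.1)

  bad <- simulation_config(
    seed = 19, n_controls = 1, n_patients = 1, grid_shape = c(16, 16, 16),
    implants_voxel = tibble::tibble(subject_id = "pat001", cx = 15, cy = 7,
                                    cz = 7, radius = 3, effect_sd = 4)
  )
  expect_error(simulate_gm_images(bad), "outside")
})

test_that("generated images survive the NIfTI round trip", {
  cfg <- simulation_config(seed = 23, n_controls = 1, n_patients = 0,
                           grid_shape = c(10, 10, 10))
  img <- simulate_gm_images(cfg)$ctrl001
  f <- tempfile(fileext = ".nii.gz")
  write_volume(img, f)
  back <- read_volume(f)
  expect_lt(max(abs(back$data - img$data)), 1e-6)
  expect_equal(back$affine, img$affine, tolerance = 1e-6)
})

test_that("longitudinal series follow the generating line", {
  cfg <- simulation_config(seed = 29)
  rates <- c(subj001 = -100)
  exact <- simulate_longitudinal(cfg, rates, n_sessions = 2,
                                 interval_months = 18, baseline = 4000,
                                 noise_sd = 0)
  expect_equal(exact$value, c(4000, 4000 - 100 * 1.5))
  expect_equal(annualized_rate(exact), -100)

  flat <- simulate_longitudinal(cfg, c(s = 0), n_sessions = 4,
                                interval_months = 6, noise_sd = 0)
  expect_equal(annualized_rate(flat), 0)

  # noisy recovery across subjects tracks the generating rates
  set.seed(30)
  gen <- rnorm(50, -100, 30)
  names(gen) <- sprintf("s%02d", 1:50)
  series <- simulate_longitudinal(cfg, gen, n_sessions = 3,
                                  interval_months = 9, noise_sd = 10)
  est <- annualized_rates(series)
  est <- est[match(names(gen), est$subject_id), ]
  expect_gt(cor(est$rate_per_year, gen), 0.9)
})
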