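test_that("FWHM-to-sigma uses the 2*sqrt(2 ln 2) constant", {
  expect_equal(fwhm_to_sigma(8) / 2, 1.69864, tolerance = 1e-5)
  expect_equal(fwhm_to_sigma(2.354820045), 1, tolerance = 1e-8)
})

test_that("zero-FWHM smoothing is the identity and mass is conserved", {
  set.seed(21)
  img <- volume_image(array(runif(12^3), c(12, 12, 12)), voxel_size = c(2, 2, 2))
  expect_identical(gaussian_smooth(img, 0)$data, img$data)

  for (fwhm in c(2, 4, 8)) {
    sm <- gaussian_smooth(img, fwhm)
    expect_equal(sum(sm$data), sum(img$data), tolerance = 1e-9)
  }
  expect_error(gaussian_smooth(img, -1), "non-negative")
})

test_that("a delta image reproduces the closed-form separable Gaussian", {
  shape <- c(17, 17, 17)
  dat <- array(0, shape); dat[9, 9, 9] <- 1
  img <- volume_image(dat, voxel_size = c(2, 2, 2))
  fwhm <- 6
  sm <- gaussian_smooth(img, fwhm)

  sigma <- fwhm_to_sigma(fwhm) / 2          # voxels
  ax <- dnorm(seq(-8, 8), sd = sigma)
  ax <- ax / sum(ax)                        # unit-sum kernel per axis
  expected <- outer(outer(ax, ax), ax)
  expect_lt(max(abs(sm$data - expected)), 1e-6)
})

test_that("anisotropic voxels get per-axis kernel widths", {
  shape <- c(21, 21, 21)
  dat <- array(0, shape); dat[11, 11, 11] <- 1
  img <- volume_image(dat, voxel_size = c(1, 2, 4))
  sm <- gaussian_smooth(img, 8)
  # spread (SD of the profile, in voxels) should scale as 1/voxel size
  profile_sd <- function(v) {
    idx <- seq_along(v) - 11
    sqrt(sum(v * idx^2) / sum(v))
  }
  sx <- profile_sd(sm$data[, 11, 11])
  sy <- profile_sd(sm$data[11, , 11])
  sz <- profile_sd(sm$data[11, 11, ])
  expect_equal(sx / sy, 2, tolerance = 0.05)
  expect_equal(sy / sz, 2, tolerance = 0.05)
})

test_that("the analysis mask excludes background and degenerate voxels", {
  set.seed(31)
  shape <- c(8, 8, 8)
  mk <- function() {
    d <- array(0.8 + rnorm(prod(shape), 0, 0.05), shape)
    d[1:2, 1:2, 1:2] <- 0          # background corner, all controls
    d[8, 8, 8] <- 0.5              # constant across controls: sd = 0
    volume_image(d)
  }
  ctrls <- replicate(6, mk(), simplify = FALSE)
  mask <- compute_analysis_mask(ctrls)
  expect_equal(mask$data[1, 1, 1], 0)
  expect_equal(mask$data[8, 8, 8], 0)
  expect_equal(mask$data[4, 4, 4], 1)

  # no floors: every voxel with any variance enters
  mask0 <- compute_analysis_mask(ctrls, gm_floor = 0, sd_floor = 0)
  expect_equal(sum(mask0$data), prod(shape))

  bad <- ctrls
  bad[[2]] <- volume_image(array(0.8, c(9, 8, 8)))
  expect_error(compute_analysis_mask(bad), "control image 2")
})

test_that("a subject equal to the control mean gives t = 0 everywhere", {
  set.seed(41)
  shape <- c(8, 8, 8)
  ctrls <- replicate(
    10, volume_image(array(0.8 + rnorm(prod(shape), 0, 0.1), shape)),
    simplify = FALSE
  )
  mean_img <- volume_image(
    array(Reduce(`+`, lapply(ctrls, function(x) x$data)) / 10, shape)
  )
  sm_less <- voxelwise_single_case(mean_img, ctrls, tails = "less", fwhm_mm = 0,
                                   gm_floor = 0, sd_floor = 0)
  inmask <- sm_less$mask$data == 1
  expect_true(all(abs(sm_less$t$data[inmask]) < 1e-10))
  expect_true(all(abs(sm_less$p$data[inmask] - 0.5) < 1e-10))

  sm_two <- voxelwise_single_case(mean_img, ctrls, tails = "two", fwhm_mm = 0,
                                  gm_floor = 0, sd_floor = 0)
  expect_true(all(abs(sm_two$p$data[inmask] - 1) < 1e-10))
})

test_that("the vectorized map equals the scalar test voxel by voxel", {
  set.seed(51)
  shape <- c(10, 10, 10)
  n <- 12
  ctrls <- replicate(
    n, volume_image(array(0.8 + rnorm(prod(shape), 0, 0.1), shape)),
    simplify = FALSE
  )
  subj <- volume_image(array(0.8 + rnorm(prod(shape), 0, 0.1), shape))
  sm <- voxelwise_single_case(subj, ctrls, tails = "less", fwhm_mm = 4)

  inmask <- which(sm$mask$data == 1)
  pick <- sample(inmask, 100)
  sm_subj <- gaussian_smooth(subj, 4)
  sm_ctrls <- lapply(ctrls, gaussian_smooth, fwhm_mm = 4)
  for (v in pick) {
    vals <- vapply(sm_ctrls, function(im) im$data[v], numeric(1))
    ch <- crawford_howell_t(sm_subj$data[v], mini_cohort(vals), tails = "less")
    expect_equal(sm$t$data[v], ch$t, tolerance = 1e-10)
    expect_equal(sm$p$data[v], ch$p, tolerance = 1e-10)
  }
})

test_that("binarization applies a strict p threshold inside the mask", {
  shape <- c(4, 4, 4)
  p <- array(0.5, shape)
  p[1, 1, 1] <- 0.004          # strictly below: in
  p[2, 1, 1] <- 0.005          # exactly at the threshold: out
  mask <- array(1, shape)
  stat <- structure(
    list(
      t = vol_from(qt(p, df = 9), shape), p = vol_from(p, shape),
      mask = vol_from(mask, shape), df = 9L, n_controls = 10L,
      tails = "less", fwhm_mm = 0
    ),
    class = "stat_map"
  )
  bin <- threshold_binarize(stat, 0.005)
  expect_equal(sum(bin$data$data), 1)
  expect_equal(bin$data$data[1, 1, 1], 1)
  expect_equal(bin$data$data[2, 1, 1], 0)
  expect_true(all(bin$data$data %in% c(0, 1)))
  expect_error(threshold_binarize(stat, 1), "between 0 and 1")

  all_null <- stat
  all_null$p <- vol_from(array(0.5, shape), shape)
  expect_equal(sum(threshold_binarize(all_null, 0.005)$data$data), 0)
})

test_that("an implanted atrophic sphere is recovered with decaying contrast", {
  cfg <- simulation_config(
    seed = 61, n_controls = 12, n_patients = 1,
    grid_shape = c(24, 24, 24), voxel_size = c(2, 2, 2),
    image_noise_sd = 0.1,
    implants_voxel = tibble::tibble(
      subject_id = "pat001", cx = 11, cy = 11, cz = 11,
      radius = 4, effect_sd = 4
    )
  )
  imgs <- simulate_gm_images(cfg)
  ctrls <- imgs[startsWith(names(imgs), "ctrl")]
  stat <- voxelwise_single_case(imgs$pat001, unname(ctrls),
                                tails = "less", fwhm_mm = 4)
  tmin_idx <- which.min(stat$t$data)
  center <- arrayInd(tmin_idx, dim(stat$t$data)) - 1   # 0-based
  expect_lt(max(abs(center - c(11, 11, 11))), 4)

  bin <- threshold_binarize(stat, 0.005)
  truth <- array(FALSE, cfg$grid_shape)
  g <- expand.grid(x = 0:23, y = 0:23, z = 0:23)
  truth[(g$x - 11)^2 + (g$y - 11)^2 + (g$z - 11)^2 <= 16] <- TRUE
  detected <- bin$data$data == 1
  dice <- 2 * sum(detected & truth) / (sum(detected) + sum(truth))
  expect_gt(dice, 0.5)
})
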