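#' Convert a Gaussian kernel FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the standard relation between
#' the full width at half maximum of a Gaussian and its SD.
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return The corresponding standard deviation, same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian smoothing of a volume image
#'
#' Separable Gaussian smoothing with a per-axis kernel SD of
#' `fwhm_to_sigma(fwhm_mm) / voxel_size[axis]` voxels, so anisotropic
#' voxels are handled correctly. Convolution is circular along each axis
#' with a kernel normalized to unit sum, which conserves the total image
#' mass exactly (modulated gray-matter images carry volume as mass, so
#' smoothing must not create or destroy it). `fwhm_mm = 0` returns the
#' input unchanged.
#'
#' @param img a [volume_image()].
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @return The smoothed `volume_image` on the same grid.
#' @export
gaussian_smooth <- function(img, fwhm_mm) {
  stopifnot(is_volume_image(img))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) {
    abort("`fwhm_mm` must be a non-negative number.")
  }
  if (fwhm_mm == 0) return(img)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / img$voxel_size
  x <- img$data
  for (axis in 1:3) {
    x <- convolve_axis_circular(x, axis, sigma_vox[axis])
  }
  out <- img
  out$data <- x
  out
}

# Circular convolution along one axis of a 3-D array with a unit-sum
# Gaussian kernel, implemented as multiplication by a (dense) circulant
# matrix: cheap for image-sized axes and exactly mass-conserving.
convolve_axis_circular <- function(x, axis, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  n <- d[axis]
  half <- max(1L, ceiling(4 * sigma))
  offsets <- seq(-half, half)
  w <- dnorm(offsets, sd = sigma)
  w <- w / sum(w)
  # column j of K holds the kernel centred on row j, wrapped modulo n
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- ((j - 1 + offsets) %% n) + 1
    for (k in seq_along(idx)) K[idx[k], j] <- K[idx[k], j] + w[k]
  }
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  m <- K %*% m
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

#' Analysis mask from the control image stack
#'
#' A voxel enters the analysis when the controls carry signal there: mean
#' control intensity at least `gm_floor` (excludes background and
#' non-gray-matter tissue in probability/volume units) and control SD at
#' least `sd_floor` (excludes degenerate voxels where the single-case t is
#' undefined).
#'
#' @param control_imgs list of [volume_image()]s on a common grid.
#' @param gm_floor minimum mean control intensity (default 0.1).
#' @param sd_floor minimum control SD (default 1e-6).
#' @return A binary `volume_image` (1 = analyzed).
#' @export
compute_analysis_mask <- function(control_imgs, gm_floor = 0.1,
                                  sd_floor = 1e-6) {
  if (length(control_imgs) < 2) {
    abort("at least 2 control images are required to form an analysis mask.")
  }
  check_common_grid(control_imgs,
                    names = paste0("control image ", seq_along(control_imgs)))
  stack <- vapply(control_imgs, function(im) as.vector(im$data),
                  numeric(length(control_imgs[[1]]$data)))
  mu <- rowMeans(stack)
  s <- row_sds(stack)
  mask <- as.numeric(mu >= gm_floor & s >= sd_floor)
  out <- control_imgs[[1]]
  out$data <- array(mask, dim(out$data))
  out
}

row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

#' Voxel-wise single-case comparison
#'
#' The whole-brain branch: the case image and every control image are
#' smoothed with the same Gaussian kernel, an analysis mask is derived from
#' the smoothed controls, and the Crawford-Howell modified t is computed at
#' every in-mask voxel with `n` = number of controls and `df = n - 1`.
#' With `tails = "less"` (the default) p is the lower-tail probability,
#' targeting gray-matter decreases (atrophy).
#'
#' @param subject_img the case's registered, modulated gray-matter
#'   [volume_image()].
#' @param control_imgs list of control images on the same grid.
#' @param tails `"less"` (default, atrophy), `"greater"` or `"two"`.
#' @param fwhm_mm smoothing kernel FWHM in mm applied to case and controls
#'   alike (0 = no smoothing).
#' @param gm_floor,sd_floor mask thresholds, see [compute_analysis_mask()].
#' @return A `stat_map` object: `t`, `p` and `mask` volume images (t and p
#'   are `NA` outside the mask), plus `df`, `n_controls`, `tails` and
#'   `fwhm_mm`.
#' @export
voxelwise_single_case <- function(subject_img, control_imgs,
                                  tails = c("less", "greater", "two"),
                                  fwhm_mm = 8, gm_floor = 0.1,
                                  sd_floor = 1e-6) {
  tails <- match.arg(tails)
  if (length(control_imgs) < 2) {
    abort("at least 2 control images are required.")
  }
  check_common_grid(
    c(list(subject_img), control_imgs),
    names = c("subject image", paste0("control image ", seq_along(control_imgs)))
  )

  subj <- gaussian_smooth(subject_img, fwhm_mm)
  ctrls <- lapply(control_imgs, gaussian_smooth, fwhm_mm = fwhm_mm)
  mask_img <- compute_analysis_mask(ctrls, gm_floor = gm_floor,
                                    sd_floor = sd_floor)
  mask <- mask_img$data == 1

  n <- length(ctrls)
  stack <- vapply(ctrls, function(im) as.vector(im$data),
                  numeric(length(subj$data)))
  mu <- rowMeans(stack)
  s <- row_sds(stack)

  t_vec <- rep(NA_real_, length(mu))
  p_vec <- rep(NA_real_, length(mu))
  idx <- which(as.vector(mask))
  t_vec[idx] <- (as.vector(subj$data)[idx] - mu[idx]) /
    (s[idx] * sqrt((n + 1) / n))
  df <- n - 1L
  p_vec[idx] <- switch(tails,
    less = pt(t_vec[idx], df),
    greater = pt(t_vec[idx], df, lower.tail = FALSE),
    two = 2 * pt(-abs(t_vec[idx]), df)
  )

  shape <- dim(subj$data)
  t_img <- subj; t_img$data <- array(t_vec, shape)
  p_img <- subj; p_img$data <- array(p_vec, shape)
  structure(
    list(
      t = t_img, p = p_img, mask = mask_img,
      df = df, n_controls = n, tails = tails, fwhm_mm = fwhm_mm,
      gm_floor = gm_floor, sd_floor = sd_floor
    ),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  nm <- sum(x$mask$data == 1)
  cat(sprintf(
    "<stat_map> df=%d (n=%d controls), tails=%s, fwhm=%g mm, %d in-mask voxels\n",
    x$df, x$n_controls, x$tails, x$fwhm_mm, nm
  ))
  if (nm > 0) {
    cat(sprintf("  t range in mask: [%.3f, %.3f]\n",
                min(x$t$data, na.rm = TRUE), max(x$t$data, na.rm = TRUE)))
  }
  invisible(x)
}

#' Threshold a voxel-wise stat map into a binary atrophy map
#'
#' Marks the voxels where the in-mask p-value is strictly below
#' `p_threshold` (the conventional exploratory threshold is p < 0.005
#' uncorrected). The direction is inherited from the stat map's tails.
#'
#' @param stat a `stat_map` from [voxelwise_single_case()].
#' @param p_threshold uncorrected p threshold, strictly applied.
#' @return A `binary_map` object: binary `data` volume plus `threshold_p`
#'   and `direction`.
#' @export
threshold_binarize <- function(stat, p_threshold = 0.005) {
  if (!is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    abort("`p_threshold` must lie strictly between 0 and 1.")
  }
  hit <- !is.na(stat$p$data) & stat$mask$data == 1 &
    stat$p$data < p_threshold
  out <- stat$p
  out$data <- array(as.numeric(hit), dim(stat$p$data))
  structure(
    list(data = out, threshold_p = p_threshold, direction = stat$tails),
    class = "binary_map"
  )
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf(
    "<binary_map> %d suprathreshold voxel(s) at p < %g (%s)\n",
    sum(x$data$data), x$threshold_p, x$direction
  ))
  invisible(x)
}

#' Plot an axial slice of a voxel-wise stat map
#'
#' @param object a `stat_map`.
#' @param slice axial (third-axis) slice index; defaults to the middle.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, slice = NULL, ...) {
  d <- dim(object$t$data)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- object$t$data[, , slice]
  df <- tibble::as_tibble(expand.grid(x = seq_len(d[1]), y = seq_len(d[2])))
  df$t <- as.vector(sl)  # column-major, matches expand.grid order
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95",
                                  high = "red", na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Single-case t map, axial slice %d (df = %d)",
                      slice, object$df)
    ) +
    ggplot2::theme_minimal()
}
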