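#' 3-D volume images
#'
#' A `volume_image` is a minimal container for a scalar 3-D grid: the voxel
#' data, a 4x4 voxel-to-world affine (RAS+ convention) and the voxel
#' dimensions in mm. Voxel indexing is 0-based through the affine; no
#' implicit reorientation is ever performed — all images entering a group
#' operation must share the same grid and affine.
#'
#' @param data numeric 3-D array of voxel values.
#' @param affine 4x4 voxel-index-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @return A `volume_image` object (list with `data`, `affine`,
#'   `voxel_size`).
#' @examples
#' img <- volume_image(array(rnorm(8^3), c(8, 8, 8)), voxel_size = c(2, 2, 2))
#' dim(img$data)
#' @export
volume_image <- function(data, affine = NULL, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  storage.mode(data) <- "double"
  vs_given <- !missing(voxel_size)
  voxel_size <- as.numeric(voxel_size)
  if (is.null(affine)) {
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
        any(voxel_size <= 0)) {
      abort("`voxel_size` must be 3 positive finite values (mm).")
    }
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(matrix(as.numeric(affine), 4, 4))
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps * 100) {
    abort("`affine` must be an invertible 4x4 matrix.")
  }
  col_norms <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (vs_given && length(voxel_size) == 3L &&
      any(abs(col_norms - voxel_size) > 1e-3)) {
    abort("`voxel_size` is inconsistent with the affine column norms (tol 1e-3).")
  }
  # the affine is authoritative for voxel geometry
  voxel_size <- col_norms
  structure(
    list(data = data, affine = affine, voxel_size = voxel_size),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  cat(sprintf(
    "  data range [%.4g, %.4g]\n",
    min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)
  ))
  invisible(x)
}

#' @rdname volume_image
#' @param x object to test.
#' @export
is_volume_image <- function(x) inherits(x, "volume_image")

#' Compare the grids of two volume images
#'
#' @param a,b `volume_image` objects.
#' @param tol elementwise affine tolerance.
#' @return `TRUE` when shapes match and affines agree elementwise.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$affine - b$affine) <= tol)
}

# Error (naming the offender) unless every image shares the first one's grid.
check_common_grid <- function(imgs, names = NULL, tol = 1e-4) {
  stopifnot(length(imgs) >= 1L)
  if (is.null(names)) names <- paste0("image ", seq_along(imgs))
  ref <- imgs[[1L]]
  for (i in seq_along(imgs)) {
    if (!same_grid(ref, imgs[[i]], tol = tol)) {
      abort(sprintf(
        "grid mismatch: %s does not share the grid/affine of %s",
        names[i], names[1]
      ))
    }
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-frame NIfTI-1 file into a [volume_image()]. A 4-D file with
#' exactly one volume is squeezed to 3-D; a 4-D file with several frames is
#' rejected (split it first — this package operates on one 3-D map per
#' subject).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `volume_image`.
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) == 4L) {
    if (d[4] != 1L) {
      abort(sprintf(
        "'%s' is 4-D with %d frames; split it into single 3-D volumes first.",
        path, d[4]
      ))
    }
    nii_data <- array(as.numeric(nii), d[1:3])
  } else if (length(d) == 3L) {
    nii_data <- array(as.numeric(nii), d)
  } else {
    abort(sprintf("'%s' is %d-D; expected a 3-D volume.", path, length(d)))
  }
  affine <- unname(matrix(as.numeric(RNifti::xform(nii)), 4, 4))
  volume_image(nii_data, affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' @param img a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param description optional free-text stored in the NIfTI description
#'   field (truncated to 79 bytes by the format).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path, description = NULL) {
  stopifnot(is_volume_image(img))
  nii <- RNifti::asNifti(img$data)
  RNifti::sform(nii) <- structure(img$affine, code = 2L)
  if (!is.null(description)) {
    nii <- RNifti::asNifti(nii, descrip = substr(description, 1, 79))
  }
  RNifti::writeNifti(nii, path)
  invisible(path)
}
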