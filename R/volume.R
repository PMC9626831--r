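#' 4D fMRI-like volume container
#'
#' A light S3 container for a 4D intensity array with voxel geometry, TR and
#' an affine. All denoising and mapping operations act on this unit.
#'
#' @param data Numeric X x Y x Z x T array.
#' @param tr Repetition time in seconds.
#' @param voxel_size Voxel edge lengths in mm (length 3, recycled).
#' @param affine 4x4 spatial transform; defaults to a scaled identity.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, tr, voxel_size = c(3.4, 3.4, 3.4), affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  fail_if(dim(data)[4] < 2, "a volume4d needs at least 2 timepoints")
  fail_if(!is.numeric(tr) || tr <= 0, "tr must be a positive number of seconds")
  voxel_size <- rep_len(voxel_size, 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(data = data, tr = tr, voxel_size = voxel_size, affine = affine),
    class = "volume4d"
  )
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d voxels, %d frames, TR %.3g s, voxels %s mm\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

# T x V matrix view of the voxels selected by a logical 3D mask.
mask_matrix <- function(volume, mask) {
  d <- dim(volume$data)
  stopifnot(all(dim(mask) == d[1:3]))
  m <- matrix(volume$data, prod(d[1:3]), d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

# Write a T x V matrix back into the masked voxels of a volume.
set_mask_matrix <- function(volume, mask, values) {
  d <- dim(volume$data)
  m <- matrix(volume$data, prod(d[1:3]), d[4])
  m[as.vector(mask), ] <- t(values)
  volume$data <- array(m, dim = d)
  volume
}

#' Mean time course over a mask
#'
#' @param volume A [volume4d()].
#' @param mask Logical 3D array.
#' @return Numeric vector of length T.
#' @export
mask_mean_ts <- function(volume, mask) {
  fail_if(!any(mask), "mask is empty")
  rowMeans(mask_matrix(volume, mask))
}

#' Spatially smooth a volume with a Gaussian kernel
#'
#' @param volume A [volume4d()].
#' @param fwhm_mm Kernel full width at half maximum in mm (scalar or length 3).
#' @return A smoothed `volume4d`.
#' @export
smooth_volume <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "volume4d"))
  volume$data <- gaussian_smooth_3d(volume$data, fwhm_mm, volume$voxel_size)
  volume
}
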