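#' PET image container
#'
#' A 3D voxel grid of activity concentration (kBq/ml) with voxel spacing and
#' origin in the phantom frame (mm, voxel-centre convention; axial slices run
#' along the third array dimension), plus free-form metadata recording how
#' the image was produced.
#'
#' @param voxels 3D numeric array, kBq/ml.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world coordinate (mm) of the centre of
#'   voxel `[1,1,1]`.
#' @param meta Named list of metadata.
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(voxels, spacing, origin = NULL, meta = list()) {
  if (length(dim(voxels)) != 3) stop_nemaiq("invalid_image", "voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_nemaiq("invalid_image", "spacing must be three positive numbers")
  }
  if (any(!is.finite(voxels))) stop_nemaiq("invalid_image", "voxel values must be finite")
  if (is.null(origin)) origin <- -(dim(voxels) - 1) / 2 * spacing
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), meta = meta),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<pet_image %d x %d x %d, spacing %g x %g x %g mm, range [%.3g, %.3g] kBq/ml>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  if (!is.null(x$meta$label)) cat(sprintf("  recon: %s\n", x$meta$label))
  invisible(x)
}

#' @export
dim.pet_image <- function(x) dim(x$voxels)

# World coordinates of voxel centres along each axis.
voxel_coords <- function(img, axis) {
  img$origin[axis] + (seq_len(dim(img$voxels)[axis]) - 1) * img$spacing[axis]
}

# Nearest voxel index for a world coordinate along an axis.
world_to_index <- function(img, x, axis) {
  round((x - img$origin[axis]) / img$spacing[axis]) + 1
}

# 1D normalised Gaussian kernel for a FWHM in mm at a given spacing.
gauss_kernel_1d <- function(fwhm_mm, spacing_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  if (sigma < 1e-8) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Convolve a 3D array along one axis with a 1D kernel, zero-padded
# boundaries. Implemented as a banded-matrix product so BLAS does the work.
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1) / 2
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1, j - r); hi <- min(n, j + r)
    C[lo:hi, j] <- kernel[(lo - j + r + 1):(hi - j + r + 1)]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), n, prod(d[-axis]))
  out <- t(C) %*% m
  aperm(array(out, d[perm]), order(perm))
}

# Separable 3D Gaussian blur with a single isotropic FWHM in mm.
gauss_blur3 <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  for (axis in 1:3) {
    arr <- conv_axis(arr, gauss_kernel_1d(fwhm_mm, spacing[axis]), axis)
  }
  arr
}

#' Total activity in an image
#'
#' Sum of voxel values times voxel volume, in kBq (voxel values are kBq/ml
#' and voxel volumes mm^3, so the result is kBq * mm^3/ml = kBq / 1000).
#'
#' @param img A [pet_image()].
#' @return Total activity (kBq).
#' @export
total_activity <- function(img) {
  sum(img$voxels) * prod(img$spacing) / 1000
}
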