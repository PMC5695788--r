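#' Convert a Gaussian kernel FWHM to its standard deviation
#'
#' The full width at half maximum of a Gaussian relates to its standard
#' deviation by FWHM = 2 sqrt(2 ln 2) sigma.
#'
#' @param fwhm_vox Full width at half maximum in voxel units (> 0).
#' @return The standard deviation sigma in voxel units.
#' @examples
#' fwhm_to_sigma(6) # 2.548
#' @export
fwhm_to_sigma <- function(fwhm_vox) {
  check_scalar_number(fwhm_vox, "fwhm_vox", lower = 0, strict_lower = TRUE)
  fwhm_vox / (2 * sqrt(2 * log(2)))
}

# Discrete 1D Gaussian kernel: density sampled at integer offsets,
# truncated at +/- 4 sigma and normalized to sum to 1.
gaussian_kernel_1d <- function(sigma) {
  radius <- ceiling(4 * sigma)
  w <- stats::dnorm(seq(-radius, radius), sd = sigma)
  w / sum(w)
}

# Banded convolution matrix applying the 1D kernel along an axis of length
# `len` with zero-padding at the boundaries (out-of-grid taps are dropped).
conv_matrix_1d <- function(len, sigma) {
  w <- gaussian_kernel_1d(sigma)
  radius <- (length(w) - 1L) / 2L
  i <- rep(seq_len(len), times = len)
  j <- rep(seq_len(len), each = len)
  off <- i - j
  k <- matrix(0, len, len)
  hit <- abs(off) <= radius
  k[cbind(i[hit], j[hit])] <- w[off[hit] + radius + 1L]
  k
}

# Pair of row/column convolution matrices for a grid.
smoothing_operators <- function(shape, fwhm_vox) {
  sigma <- fwhm_to_sigma(fwhm_vox)
  list(kr = conv_matrix_1d(shape[1L], sigma),
       kc = conv_matrix_1d(shape[2L], sigma))
}

#' Smooth a 2D grid field with an isotropic Gaussian kernel
#'
#' Convolves the full rectangular grid with a separable 2D Gaussian of the
#' given FWHM (kernel truncated at 4 sigma, zero-padding at the grid
#' boundary), then optionally restricts the result to in-mask voxels.
#' The operator is linear and preserves a constant field away from the
#' boundary.
#'
#' @param values Numeric matrix on the full grid (rows x cols).
#' @param fwhm_vox Kernel FWHM in voxel units (> 0).
#' @param mask Optional [make_mask()] object; when supplied the return
#'   value is the per-voxel vector over `mask$idx`, otherwise the full
#'   smoothed grid matrix.
#' @return Smoothed grid matrix, or in-mask voxel vector when `mask` is
#'   given.
#' @export
smooth_field <- function(values, fwhm_vox, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("`values` must be a numeric matrix on the full grid")
  }
  ops <- smoothing_operators(dim(values), fwhm_vox)
  sm <- ops$kr %*% values %*% t(ops$kc)
  if (is.null(mask)) {
    return(sm)
  }
  stopifnot(inherits(mask, "grid_mask"))
  if (!all(dim(values) == mask$shape)) {
    stop_invalid("`values` dimensions do not match the mask grid")
  }
  sm[mask$idx]
}

# Per-cell standard deviation of the smoothing operator applied to unit
# white noise: separable sum of squared kernel weights. Used to renormalize
# smoothed noise fields back to unit variance.
smoothed_noise_sd <- function(shape, fwhm_vox) {
  ops <- smoothing_operators(shape, fwhm_vox)
  sqrt(outer(rowSums(ops$kr^2), rowSums(ops$kc^2)))
}
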