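#' Generate a simulated cohort from a designed effect field
#'
#' Draws `n` subjects. The behavioral variable y is iid standard normal.
#' Each subject's activation noise is an iid standard-normal grid field,
#' smoothed with `noise_fwhm_vox` (so it retains spatial autocorrelation),
#' restricted to the mask, and divided by the deterministic per-voxel
#' standard deviation of smoothed white noise so each voxel's noise has
#' unit variance. Activation at voxel v is then
#' \deqn{x_v = \rho_v y + \sqrt{1 - \rho_v^2}\, \epsilon_v,}
#' which makes the population correlation of x_v with y exactly the
#' designed rho_v. Mean activation is 0 everywhere; Pearson correlation is
#' location-invariant, so means are irrelevant to every metric computed
#' downstream.
#'
#' @param field An [make_effect_field()] object.
#' @param n Number of subjects (>= 4; the correlation test needs n - 2 >=
#'   2 degrees of freedom).
#' @param noise_fwhm_vox Noise smoothing FWHM in voxels; defaults to the
#'   scenario's `fwhm_vox`.
#' @param seed RNG seed; the same seed reproduces the cohort bitwise.
#' @return An object of class `cohort_sample`: list with `n`, `behavior`
#'   (length-n vector), `activity` (n x n_voxels matrix), `field`, `seed`.
#' @examples
#' f <- make_effect_field(scenario_spec("SL", shape = c(30, 30),
#'                                      target_voxels = 600))
#' co <- generate_cohort(f, n = 50, seed = 7)
#' dim(co$activity)
#' @export
generate_cohort <- function(field, n, noise_fwhm_vox = field$spec$fwhm_vox,
                            seed = 1L) {
  stopifnot(inherits(field, "effect_field"))
  n <- check_count(n, "n", lower = 4L)
  check_scalar_number(noise_fwhm_vox, "noise_fwhm_vox", 0,
                      strict_lower = TRUE)
  mask <- field$mask
  shape <- mask$shape
  rho <- field$rho
  ops <- smoothing_operators(shape, noise_fwhm_vox)
  sd_vox <- smoothed_noise_sd(shape, noise_fwhm_vox)[mask$idx]
  mix <- sqrt(1 - rho^2)
  block <- 500L # fixed so the RNG stream (hence the cohort) is reproducible
  with_seed(seed, {
    y <- stats::rnorm(n)
    activity <- matrix(0, n, mask$n_voxels)
    done <- 0L
    while (done < n) {
      b <- min(block, n - done)
      eps <- smooth_noise_block(shape, b, ops)[mask$idx, , drop = FALSE]
      eps <- eps / sd_vox # recycles down columns: per-voxel renormalization
      rows <- done + seq_len(b)
      activity[rows, ] <- rep(y[rows], times = mask$n_voxels) *
        rep(rho, each = b) + t(eps) * rep(mix, each = b)
      done <- done + b
    }
    structure(
      list(n = n, behavior = y, activity = activity, field = field,
           seed = as.integer(seed)),
      class = "cohort_sample"
    )
  })
}

# Draw `b` iid standard-normal grid fields and smooth each one, batched
# through BLAS: rows first on the (nr, nc*b) unfolding, then columns on
# the (nc, nr*b) unfolding. Returns an (nr*nc, b) matrix of grid cells.
smooth_noise_block <- function(shape, b, ops) {
  nr <- shape[1L]; nc <- shape[2L]
  a <- array(stats::rnorm(nr * nc * b), c(nr, nc, b))
  a <- array(ops$kr %*% matrix(a, nr, nc * b), c(nr, nc, b))
  a <- matrix(aperm(a, c(2L, 1L, 3L)), nc, nr * b)
  a <- aperm(array(ops$kc %*% a, c(nc, nr, b)), c(2L, 1L, 3L))
  matrix(a, nr * nc, b)
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf("<cohort_sample> n = %d subjects x %d voxels (%s, seed %d)\n",
              x$n, x$field$mask$n_voxels, x$field$spec$kind, x$seed))
  invisible(x)
}

#' Draw a random subsample of a cohort
#'
#' Selects `n_sub` distinct subjects uniformly without replacement,
#' deterministically for a given seed.
#'
#' @param parent A [generate_cohort()] object.
#' @param n_sub Subsample size, between 4 and `parent$n`.
#' @param seed RNG seed.
#' @return An object of class `subsample_index`: list with `indices`,
#'   `n_sub`, and `parent_n`.
#' @export
draw_subsample <- function(parent, n_sub, seed = 1L) {
  stopifnot(inherits(parent, "cohort_sample"))
  n_sub <- check_count(n_sub, "n_sub", lower = 4L)
  if (n_sub > parent$n) {
    stop_invalid("n_sub (%d) exceeds the cohort size (%d)", n_sub, parent$n)
  }
  idx <- with_seed(seed, sample.int(parent$n, n_sub))
  structure(list(indices = idx, n_sub = n_sub, parent_n = parent$n),
            class = "subsample_index")
}
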