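# Small synthetic objects for unit tests, built through the package's
# constructors where possible and by hand where a test needs a field or
# map the constructors would not produce (e.g. an all-null field).

small_mask <- function(shape = c(20L, 20L), target = 300L) {
  make_mask(shape, target)
}

# Hand-built effect field with arbitrary designed rho values.
synthetic_field <- function(rho, mask = small_mask(), band = c(0.05, 0.14),
                            fwhm = 3) {
  stopifnot(length(rho) == mask$n_voxels)
  spec <- scenario_spec("WD", r_band = band, fwhm_vox = fwhm,
                        shape = mask$shape, target_voxels = mask$n_voxels)
  structure(
    list(mask = mask, rho = rho,
         band_mask = abs(rho) >= band[1] & abs(rho) <= band[2],
         spec = spec),
    class = "effect_field"
  )
}

# Hand-built cohort wrapping given behavior / activity data.
synthetic_cohort <- function(y, x, field = NULL) {
  x <- as.matrix(x)
  if (is.null(field)) {
    mask <- make_mask(c(1L, ncol(x)), ncol(x))
    field <- synthetic_field(rep(0, ncol(x)), mask)
  }
  structure(
    list(n = length(y), behavior = y, activity = x, field = field,
         seed = NA_integer_),
    class = "cohort_sample"
  )
}

# Stat map with prescribed p-values (r back-filled to match).
statmap_from_p <- function(p, n = 30L, mask = NULL) {
  if (is.null(mask)) mask <- make_mask(c(1L, length(p)), length(p))
  tq <- qt(1 - p / 2, df = n - 2)
  r <- tq / sqrt(tq^2 + n - 2)
  structure(list(n = n, r = r, t = tq, p = p, mask = mask),
            class = "voxel_stat_map")
}

sig_from_logical <- function(sig, mask, spec = threshold_spec(), n = 30L) {
  structure(list(sig = sig, threshold = spec, n = n, mask = mask),
            class = "significance_map")
}

# Scaled-down scenarios on a 20x20 grid for fast experiment tests.
small_wd_spec <- function(seed = 1L) {
  scenario_spec("WD", shape = c(20L, 20L), target_voxels = 300L,
                fwhm_vox = 3, seed = seed)
}

small_sl_spec <- function(seed = 1L) {
  scenario_spec("SL", effect_fraction = 0.1, shape = c(20L, 20L),
                target_voxels = 300L, fwhm_vox = 3, seed = seed)
}
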