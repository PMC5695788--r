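#' Balance type II against type I error counts by threshold search
#'
#' Given an effect field, partitions its voxels into effect voxels
#' (|rho| >= `band_min`) and comparison voxels (|rho| < `band_min`) and
#' finds the uncorrected two-sided threshold alpha at which the ratio of
#' expected error counts
#' \deqn{FN(\alpha)/FP(\alpha) = \texttt{target\_ratio},}
#' where FN is the expected number of non-significant effect voxels and
#' FP the expected number of significant comparison voxels at sample size
#' `n`. The conventional 20% type II / 5% type I rates motivate a target
#' ratio of 4. The ratio is continuous and strictly decreasing in alpha,
#' so the root is unique; it is located by bisection on (1e-6, 0.999).
#'
#' In `"analytic"` mode the expected counts are voxel-wise sums of
#' [power_correlation()] (Fisher method). In `"simulation"` mode they are
#' estimated from `n_reps` freshly simulated cohorts of size `n`, from
#' whose per-voxel p-values the counts at any alpha follow directly.
#'
#' @param field An [make_effect_field()] object containing both effect
#'   and comparison voxels.
#' @param n Sample size of the hypothetical study.
#' @param target_ratio Desired FN/FP count ratio (> 0), e.g. 4.
#' @param band_min |rho| cutoff separating effect from comparison voxels
#'   (default 0.05).
#' @param mode `"analytic"` or `"simulation"`.
#' @param n_reps Simulated cohorts in `"simulation"` mode (default 2000).
#' @param seed RNG seed for `"simulation"` mode.
#' @param tol Bisection tolerance on alpha (default 1e-5).
#' @return The balancing uncorrected p-threshold alpha, with attributes
#'   `fn` and `fp` giving the expected error counts at the returned
#'   threshold.
#' @export
balance_error_ratio <- function(field, n, target_ratio, band_min = 0.05,
                                mode = c("analytic", "simulation"),
                                n_reps = 2000L, seed = 1L, tol = 1e-5) {
  stopifnot(inherits(field, "effect_field"))
  mode <- match.arg(mode)
  n <- check_count(n, "n", lower = 4L)
  check_scalar_number(target_ratio, "target_ratio", 0, strict_lower = TRUE)
  check_scalar_number(band_min, "band_min", 0, 1, strict_lower = TRUE)
  eff <- abs(field$rho) >= band_min
  cmp <- !eff
  if (!any(cmp)) {
    stop_invalid("no comparison voxels with |rho| < %g: ratio undefined",
                 band_min)
  }
  if (!any(eff)) {
    stop_invalid("no effect voxels with |rho| >= %g", band_min)
  }

  counts <- if (mode == "analytic") {
    rho_eff <- field$rho[eff]
    rho_cmp <- field$rho[cmp]
    function(alpha) {
      list(fn = sum(1 - power_correlation(rho_eff, n, alpha, "fisher")),
           fp = sum(power_correlation(rho_cmp, n, alpha, "fisher")))
    }
  } else {
    n_reps <- check_count(n_reps, "n_reps", lower = 2L)
    p_eff <- matrix(0, n_reps, sum(eff))
    p_cmp <- matrix(0, n_reps, sum(cmp))
    for (rep in seq_len(n_reps)) {
      co <- generate_cohort(field, n, seed = seed + rep)
      p <- pearson_map(co$behavior, co$activity)$p
      p_eff[rep, ] <- p[eff]
      p_cmp[rep, ] <- p[cmp]
    }
    function(alpha) {
      list(fn = sum(p_eff >= alpha) / n_reps,
           fp = sum(p_cmp < alpha) / n_reps)
    }
  }

  ratio_gap <- function(alpha) {
    ct <- counts(alpha)
    if (ct$fp == 0) Inf else ct$fn / ct$fp - target_ratio
  }
  lo <- 1e-6; hi <- 0.999
  g_lo <- ratio_gap(lo); g_hi <- ratio_gap(hi)
  if (!(g_lo > 0 && g_hi < 0)) {
    stop_invalid(
      "FN/FP ratio never crosses %g on (%g, %g): bracket ratios %.4g and %.4g",
      target_ratio, lo, hi, g_lo + target_ratio, g_hi + target_ratio)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ratio_gap(mid) > 0) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2
  ct <- counts(alpha)
  structure(alpha, fn = ct$fn, fp = ct$fp)
}
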