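#' Define the set of "true effect" voxels
#'
#' The outcome metrics need a ground-truth voxel set. Three definitions
#' are supported:
#' * `"designed_any"` (default): every voxel with a nonzero designed
#'   rho. This is the definition the simulation metrics use by default.
#' * `"designed_band"`: voxels with |rho| >= `band_min`.
#' * `"fullsample_sig"`: voxels significant in the full cohort under a
#'   given threshold (pass the full-cohort [threshold()] result as
#'   `full_sig`).
#'
#' @param field An [make_effect_field()] object.
#' @param mode Truth definition, see above.
#' @param band_min |rho| cutoff for `"designed_band"`.
#' @param full_sig Full-cohort [threshold()] result for
#'   `"fullsample_sig"`.
#' @return An object of class `truth_set` with logical `true_mask`.
#' @export
truth_set <- function(field,
                      mode = c("designed_any", "designed_band",
                               "fullsample_sig"),
                      band_min = NULL, full_sig = NULL) {
  stopifnot(inherits(field, "effect_field"))
  mode <- match.arg(mode)
  true_mask <- switch(mode,
    designed_any = field$rho != 0,
    designed_band = {
      if (is.null(band_min)) band_min <- field$spec$r_band[1L]
      check_scalar_number(band_min, "band_min", 0, 1, strict_lower = TRUE)
      abs(field$rho) >= band_min
    },
    fullsample_sig = {
      if (!inherits(full_sig, "significance_map")) {
        stop_invalid("`full_sig` must be a significance_map for mode 'fullsample_sig'")
      }
      full_sig$sig
    }
  )
  structure(list(mode = mode, true_mask = true_mask,
                 band_min = band_min, n_true = sum(true_mask)),
            class = "truth_set")
}

check_sig <- function(sig) {
  if (!inherits(sig, "significance_map")) {
    stop_invalid("expected a significance_map")
  }
  invisible(sig)
}

check_truth <- function(truth) {
  if (!inherits(truth, "truth_set")) {
    stop_invalid("expected a truth_set")
  }
  if (truth$n_true == 0L) {
    stop_invalid("truth set is empty: metric undefined")
  }
  invisible(truth)
}

#' Average statistical power of a significance map
#'
#' Fraction of true-effect voxels that attained significance.
#'
#' @param sig A [threshold()] result.
#' @param truth A [truth_set()]; must be nonempty.
#' @return Fraction in \[0, 1\].
#' @export
average_power <- function(sig, truth) {
  check_sig(sig); check_truth(truth)
  sum(sig$sig & truth$true_mask) / truth$n_true
}

#' At-least-one statistical power indicator
#'
#' `TRUE` when at least one true-effect voxel is significant. Averaged
#' over repetitions this is the power to detect at least one true effect.
#'
#' @inheritParams average_power
#' @return Logical.
#' @export
at_least_one <- function(sig, truth) {
  check_sig(sig); check_truth(truth)
  any(sig$sig & truth$true_mask)
}

#' Mean absolute effect size among significant voxels
#'
#' The mean of |r| over voxels attaining significance: conditional on
#' significance this overestimates the designed effects (winner's curse),
#' and under an uncorrected threshold it is structurally bounded below by
#' [critical_r()].
#'
#' @param statmap The [correlate()] result the map was thresholded from.
#' @param sig The matching [threshold()] result.
#' @return Mean |r| over significant voxels, or `NA` when no voxel is
#'   significant (undefined, not an error; callers exclude and count
#'   these).
#' @export
mean_significant_effect <- function(statmap, sig) {
  stopifnot(inherits(statmap, "voxel_stat_map"))
  check_sig(sig)
  if (!any(sig$sig)) {
    return(NA_real_)
  }
  mean(abs(statmap$r[sig$sig]))
}

#' Percentage of in-mask voxels attaining significance
#'
#' @param sig A [threshold()] result.
#' @return Percent in \[0, 100\].
#' @export
percent_significant <- function(sig) {
  check_sig(sig)
  100 * sum(sig$sig) / length(sig$sig)
}

#' Dice overlap of two significance maps
#'
#' 2 |A intersect B| / (|A| + |B|): the replication-consistency metric
#' between the significant-voxel sets of two studies.
#'
#' @param sig_i,sig_j [threshold()] results on the same mask.
#' @return Dice coefficient in \[0, 1\], or `NA` when both maps are
#'   empty.
#' @export
dice <- function(sig_i, sig_j) {
  check_sig(sig_i); check_sig(sig_j)
  if (length(sig_i$sig) != length(sig_j$sig) ||
      !identical(sig_i$mask$idx, sig_j$mask$idx)) {
    stop_invalid("significance maps are defined on different masks")
  }
  tot <- sum(sig_i$sig) + sum(sig_j$sig)
  if (tot == 0L) {
    return(NA_real_)
  }
  2 * sum(sig_i$sig & sig_j$sig) / tot
}

#' Selectivity of a significance map with respect to a region
#'
#' One minus the fraction of out-of-region voxels that are significant:
#' 1 means the effect is confined to the region of interest, 0 means the
#' whole rest of the slice shows it. This index is this package's own
#' operationalization of regional selectivity.
#'
#' @param sig A [threshold()] result.
#' @param roi Logical per-voxel vector, nonempty and a strict subset of
#'   the mask.
#' @return Fraction in \[0, 1\].
#' @export
selectivity_index <- function(sig, roi) {
  check_sig(sig)
  if (!is.logical(roi) || length(roi) != length(sig$sig)) {
    stop_invalid("`roi` must be a logical per-voxel vector on the mask")
  }
  n_out <- sum(!roi)
  if (!any(roi) || n_out == 0L) {
    stop_invalid("`roi` must be a nonempty strict subset of the mask")
  }
  1 - sum(sig$sig & !roi) / n_out
}
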