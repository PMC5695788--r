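#' Mass-univariate Pearson correlation testing
#'
#' Correlates each voxel's activation column with the behavioral variable
#' and computes the two-sided p-value from the t distribution with n - 2
#' degrees of freedom, t = r sqrt((n - 2) / (1 - r^2)).
#'
#' Constant activation columns have no defined correlation; they are
#' reported as r = 0, p = 1 with a warning rather than failing the whole
#' map.
#'
#' @param sample A [generate_cohort()] object.
#' @param subset Optional [draw_subsample()] object or integer vector of
#'   subject rows; `NULL` uses the full cohort.
#' @return An object of class `voxel_stat_map`: list with `n`, `r`, `t`,
#'   `p` (per-voxel vectors) and `mask`.
#' @export
correlate <- function(sample, subset = NULL) {
  stopifnot(inherits(sample, "cohort_sample"))
  idx <- if (is.null(subset)) {
    seq_len(sample$n)
  } else if (inherits(subset, "subsample_index")) {
    subset$indices
  } else {
    as.integer(subset)
  }
  if (length(idx) < 4L) {
    stop_invalid("correlation testing needs at least 4 subjects")
  }
  res <- pearson_map(sample$behavior[idx],
                     sample$activity[idx, , drop = FALSE])
  structure(
    c(res, list(mask = sample$field$mask)),
    class = "voxel_stat_map"
  )
}

# Vectorized Pearson r / t / p of each column of X against y.
pearson_map <- function(y, x) {
  n <- length(y)
  yc <- y - mean(y)
  xc <- x - rep(colMeans(x), each = n)
  ssx <- colSums(xc^2)
  ssy <- sum(yc^2)
  const <- ssx <= 0 | ssy <= 0
  denom <- sqrt(ssx * ssy)
  denom[const] <- 1
  r <- as.vector(crossprod(yc, xc)) / denom
  r <- pmin(1, pmax(-1, r))
  if (any(const)) {
    warning(sprintf("%d constant activation column(s): returning r = 0, p = 1",
                    sum(const)), call. = FALSE)
    r[const] <- 0
  }
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  t[abs(r) == 1] <- sign(r[abs(r) == 1]) * Inf
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[const] <- 1
  list(n = n, r = r, t = t, p = p)
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("<voxel_stat_map> n = %d, %d voxels, |r| max %.3f, p min %.2e\n",
              x$n, length(x$r), max(abs(x$r)), min(x$p)))
  invisible(x)
}

#' Critical absolute correlation of the two-sided test
#'
#' The uncorrected two-sided test at level alpha rejects exactly when
#' |r| >= r*, with r* = t* / sqrt(t*^2 + n - 2) and t* the upper alpha/2
#' quantile of the t distribution with n - 2 degrees of freedom.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param n Sample size (>= 4).
#' @return The critical |r| threshold.
#' @examples
#' critical_r(0.01, 30) # 0.463
#' @export
critical_r <- function(alpha, n) {
  check_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  n <- check_count(n, "n", lower = 4L)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Specify a significance thresholding rule
#'
#' @param method `"uncorrected"` (voxel-wise p < alpha) or `"fdr_bh"`
#'   (Benjamini-Hochberg step-up over all in-mask p-values at level q).
#' @param level alpha for `"uncorrected"` (default 0.01) or q for
#'   `"fdr_bh"` (default 0.05). Tests are two-sided throughout.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("uncorrected", "fdr_bh"),
                           level = NULL) {
  method <- match.arg(method)
  if (is.null(level)) {
    level <- if (method == "uncorrected") 0.01 else 0.05
  }
  check_scalar_number(level, "level", 0, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  structure(list(method = method, level = level, tails = "two"),
            class = "threshold_spec")
}

#' Threshold a voxel statistic map
#'
#' Uncorrected thresholding declares voxels with p < alpha significant
#' (equivalently |r| >= [critical_r()]). Benjamini-Hochberg FDR applies
#' the step-up procedure over all in-mask p-values: the k smallest
#' p-values are rejected, with k the largest index such that p_(k) <= k
#' q / m.
#'
#' @param statmap A [correlate()] result.
#' @param spec A [threshold_spec()].
#' @return An object of class `significance_map`: list with `sig`
#'   (logical per voxel), `threshold`, `n`, and `mask`.
#' @export
threshold <- function(statmap, spec = threshold_spec()) {
  stopifnot(inherits(statmap, "voxel_stat_map"),
            inherits(spec, "threshold_spec"))
  sig <- if (spec$method == "uncorrected") {
    statmap$p < spec$level
  } else {
    stats::p.adjust(statmap$p, method = "BH") <= spec$level
  }
  structure(
    list(sig = sig, threshold = spec, n = statmap$n, mask = statmap$mask),
    class = "significance_map"
  )
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("<significance_map> %s level %g: %d / %d voxels significant\n",
              x$threshold$method, x$threshold$level, sum(x$sig),
              length(x$sig)))
  invisible(x)
}
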