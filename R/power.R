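# Gauss hypergeometric 2F1(1/2, 1/2; c; z) by power series; converges for
# z in [0, 1), which covers z = (1 + rho r)/2 with |rho| < 1.
hyp2f1_half <- function(c, z) {
  vapply(z, function(zi) {
    term <- 1; s <- 1; k <- 0
    while (abs(term) > 1e-15 * abs(s) && k < 20000) {
      term <- term * (0.5 + k)^2 / ((c + k) * (k + 1)) * zi
      s <- s + term
      k <- k + 1
    }
    s
  }, numeric(1))
}

# Exact sampling density of the Pearson correlation r for a bivariate
# normal population with correlation rho and sample size n (Hotelling's
# hypergeometric form).
r_sampling_density <- function(r, rho, n) {
  lconst <- log(n - 2) - 0.5 * log(2 * pi) + lgamma(n - 1) - lgamma(n - 0.5)
  lf <- lconst + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - (n - 1.5) * log1p(-rho * r)
  exp(lf) * hyp2f1_half(n - 0.5, (1 + rho * r) / 2)
}

#' Power of the two-sided Pearson correlation test
#'
#' Probability that a sample of size `n` from a bivariate normal
#' population with correlation `rho` yields |r| >= [critical_r()]
#' (two-sided test at level `alpha`).
#'
#' `method = "exact"` integrates the exact sampling density of r over the
#' rejection region by adaptive quadrature. `method = "fisher"` uses the
#' Fisher-z normal approximation: z(r) is treated as normal with mean
#' atanh(rho) (+ rho / (2 (n - 1)) when `bias_correction` is on) and
#' standard deviation 1 / sqrt(n - 3).
#'
#' @param rho Population correlation(s) in (-1, 1); vectorized.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level in (0, 1).
#' @param method `"exact"` or `"fisher"`.
#' @param bias_correction Apply the mean-bias term in the Fisher
#'   approximation (default `TRUE`; ignored for `"exact"`).
#' @return Power value(s) in \[0, 1\].
#' @examples
#' power_correlation(0.3, 30, 0.001) # about 0.042
#' @export
power_correlation <- function(rho, n, alpha, method = c("exact", "fisher"),
                              bias_correction = TRUE) {
  method <- match.arg(method)
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop_invalid("`rho` must lie strictly inside (-1, 1)")
  }
  rc <- critical_r(alpha, n) # validates alpha and n
  if (method == "fisher") {
    zc <- atanh(rc)
    zr <- atanh(rho) + if (bias_correction) rho / (2 * (n - 1)) else 0
    sd <- 1 / sqrt(n - 3)
    return(stats::pnorm((zr - zc) / sd) + stats::pnorm((-zc - zr) / sd))
  }
  vapply(rho, function(rh) {
    if (rh == 0) return(alpha)
    up <- stats::integrate(r_sampling_density, rc, 1, rho = rh, n = n,
                           rel.tol = 1e-8, abs.tol = 1e-10)$value
    lo <- stats::integrate(r_sampling_density, -1, -rc, rho = rh, n = n,
                           rel.tol = 1e-8, abs.tol = 1e-10)$value
    min(1, up + lo)
  }, numeric(1))
}

#' Fisher-z confidence interval for a correlation
#'
#' tanh(atanh(r) +/- z_(1 + level)/2 / sqrt(n - 3)).
#'
#' @param r Sample correlation with |r| <= 1.
#' @param n Sample size (>= 4).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(low, high)`. For |r| = 1 the interval
#'   degenerates to `(r, r)` with a warning.
#' @examples
#' ci_correlation(0, 100) # about (-0.196, 0.196)
#' @export
ci_correlation <- function(r, n, level = 0.95) {
  check_scalar_number(r, "r", -1, 1)
  n <- check_count(n, "n", lower = 4L)
  check_scalar_number(level, "level", 0, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  if (abs(r) == 1) {
    warning("|r| = 1: confidence interval degenerates to a point",
            call. = FALSE)
    return(c(low = r, high = r))
  }
  zc <- stats::qnorm((1 + level) / 2) / sqrt(n - 3)
  c(low = tanh(atanh(r) - zc), high = tanh(atanh(r) + zc))
}
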