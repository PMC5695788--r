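---
title: "Simulating power, inflation, and replication in voxel-wise correlation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating power, inflation, and replication in voxel-wise correlation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelpower)
```

## The question the simulator answers

A mass-univariate brain–behavior study computes one Pearson correlation
per voxel between activation and a behavioral variable, thresholds the
map, and reports the surviving voxels. The quality of that report
depends jointly on the sample size, the per-voxel effect sizes, their
spatial distribution, and the threshold. `voxelpower` makes those four
ingredients explicit and fully controllable, so the behavior of the
pipeline — detection rates, effect-size inflation, apparent spatial
extent, replication overlap — can be measured rather than guessed.

## The data-generating model

### Analysis domain

The domain is a 2D grid (default 90 × 70) with an elliptical "brain
slice" mask of exactly 4,713 voxels. `make_mask()` ranks cells by scaled
elliptical distance from the grid center and keeps the closest
`target_voxels` cells, with row-major tie-breaking, so the count is
exact and the mask deterministic and 4-connected.

### Designed effect fields

An effect field assigns each in-mask voxel a population correlation
$\rho_v \in (-1, 1)$. Two scenarios represent the two common beliefs
about brain–behavior associations:

* **Weak Diffuse (WD).** An iid standard-normal grid field is smoothed
  (Gaussian kernel, FWHM 6 voxels) and restricted to the mask. The
  magnitudes are then rescaled *monotonically by rank*: the largest
  `round(0.72 × 4713) = 3393` magnitudes are mapped linearly onto
  $[0.05, 0.14]$ and the rest into the open interval $(0.005, 0.05)$,
  with signs inherited from the smoothed field. Every voxel therefore
  carries a small but nonzero designed effect. The rank-mapping turns
  "around 72%" into an exact, testable count while preserving the
  smooth spatial layout.
* **Strong Localized (SL).** Four circular Gaussian-profile blobs (two
  positive, two negative) sit at fixed, well-separated positions inside
  the mask (offsets of ±0.2 of each grid dimension from center, blob
  profile $\exp(-d^2/2s^2)$ with $s = 3$ voxels). The
  `round(0.038 × 4713) = 179` cells with the highest blob profile are
  selected and mapped by within-blob rank linearly onto $[0.61, 0.80]$,
  centers highest; all other voxels are exactly zero. The number and
  placement of blobs is this package's concrete choice of a "few
  strong focal effects" layout; any compact, well-separated layout with
  the same magnitude band behaves equivalently for every metric that
  does not reference blob geometry.

The WD sub-band magnitudes in $(0.005, 0.05)$ deserve a note: treating
the non-band 28% as *exactly* null would change the metrics (those
voxels would leave the truth set and enter the false-positive pool). A
smooth field has no reason to vanish exactly off its upper quantiles, so
the package continues the rank mapping below the band instead. This is
also what makes the default truth definition (below) consistent: with
all 4,713 voxels carrying some effect, average power in WD is diluted by
the barely-detectable majority — which is the phenomenon of interest.

### Cohort generation

`generate_cohort()` draws the behavioral variable $y \sim N(0,1)$ and,
per subject, a noise grid field that is smoothed with the same FWHM,
restricted to the mask, and divided by the closed-form per-voxel
standard deviation of smoothed white noise (the square root of the sum
of squared kernel weights, separable across axes). Activation is the
mixture

$$x_v = \rho_v\, y + \sqrt{1 - \rho_v^2}\; \epsilon_v ,$$

whose population correlation with $y$ is exactly $\rho_v$ — not
approximately, which is what permits sharp regression tests (realized
$r$ deviates from $\rho_v$ by pure sampling noise, $O(1/\sqrt n)$).
Mean activation is zero everywhere; Pearson correlation is
location-invariant, so adding a mean surface would change no metric.
Smoothing uses zero-padding at the grid boundary with the kernel
truncated at $4\sigma$ and renormalized to unit sum; the variance
renormalization absorbs the boundary attenuation.

Subjects are generated in fixed blocks of 500 so the RNG stream — and
hence the cohort — is bitwise reproducible for a given seed regardless
of memory conditions.

### What the generator does and does not emulate

It reproduces: exactly specified per-voxel effect sizes, spatial
autocorrelation of noise at a chosen smoothness, Gaussian marginals, and
the full-sample/subsample design. It does not emulate: 3D anatomy,
inter-subject variance heterogeneity, non-Gaussian behavioral measures,
outliers, temporal/hemodynamic structure, or site effects. Passing
tests therefore validate the statistical pipeline under idealized
conditions; on real data, outliers and heteroscedasticity generally make
small-sample correlation estimates *worse* than simulated here.

## The testing pipeline

`correlate()` computes per-voxel $r$, $t = r\sqrt{(n-2)/(1-r^2)}$, and
the two-sided p-value from the $t_{n-2}$ distribution. Tests are
two-sided throughout: both signs of effects exist by construction, so a
one-sided convention would be incoherent. Constant activation columns
(possible only in degenerate inputs) yield $r = 0, p = 1$ with a
warning rather than an error, so one bad voxel cannot void a map.

`threshold()` supports the uncorrected rule $p < \alpha$ (default
$\alpha = .01$; equivalent to $|r| \ge$ `critical_r(alpha, n)`, an
identity tested exactly) and Benjamini–Hochberg FDR at level $q$
(default 0.05), delegated to `stats::p.adjust`. Ties in p-values are
handled by the standard largest-k step-up rule.

## Outcome metrics and the truth set

Metrics need a definition of "true effect". The default,
`designed_any` ($\rho_v \neq 0$), is the only definition that is
simultaneously faithful to both scenarios: in WD the denominator
includes the sub-band voxels (power is correctly diluted), while in SL
it is exactly the 179 blob voxels with no chance-significant null
voxels inflating it. `designed_band` (a $|\rho|$ cutoff) and
`fullsample_sig` (significance in the full cohort) are provided for
sensitivity analysis, since "the full-sample effects" is itself an
ambiguous notion once thresholds enter.

Per repetition the package records average power, the at-least-one
indicator, mean $|r|$ over significant voxels (undefined when nothing is
significant; such repetitions are excluded from curve means with their
count reported), percent significant voxels, and the Dice coefficient
between consecutive repetition pairs — (1,2), (3,4), … — so each Dice
value compares two independent "studies". `summarize_records()`
aggregates each metric per sample size by its mean and 2.5/97.5
percentiles across repetitions (a percentile description of the
sampling distribution; no normality assumption).

The `selectivity_index()` — one minus the fraction of out-of-ROI voxels
significant — is this package's own simple operationalization of
regional selectivity (1 = effect confined to the ROI, 0 = the whole
slice shows it), and is documented as such.

## Analytic calculators

`power_correlation()` offers two methods:

* `"exact"` integrates the exact sampling density of $r$ under a
  bivariate normal population (Hotelling's hypergeometric form,
  $f(r) \propto (1-\rho^2)^{(n-1)/2}(1-r^2)^{(n-4)/2}(1-\rho r)^{-(n-3/2)}
  {}_2F_1(\tfrac12,\tfrac12;n-\tfrac12;\tfrac{1+\rho r}2)$)
  over the two-sided rejection region by adaptive quadrature
  (rel. tol. 1e-8). The ${}_2F_1$ series converges absolutely for the
  argument range that arises ($z = (1+\rho r)/2 < 1$).
* `"fisher"` applies the Fisher-z normal approximation with mean
  $\operatorname{atanh}\rho + \rho/(2(n-1))$ (the bias term is on by
  default and can be disabled) and standard deviation $1/\sqrt{n-3}$.
  It is vectorized and used where thousands of voxel-wise powers are
  needed.

At the calibration point $\rho = 0.3$, $n = 30$, $\alpha = .001$ the
exact method gives 0.0416, the Fisher method 0.0417 with and 0.0393
without the bias term, and a $10^6$-draw Monte-Carlo oracle agrees with
the exact value within simulation error — about 4% power, the
motivating order of magnitude for typical small-sample fMRI correlation
analyses.

`ci_correlation()` is the standard Fisher-z interval
$\tanh(\operatorname{atanh} r \pm z_{(1+\gamma)/2}/\sqrt{n-3})$.

## Balancing error counts

`balance_error_ratio()` finds the uncorrected $\alpha$ at which

$$\frac{FN(\alpha)}{FP(\alpha)} = \text{target ratio},$$

with $FN$ the expected number of missed effect voxels
($|\rho| \ge$ `band_min`, default 0.05) and $FP$ the expected number of
significant comparison voxels ($|\rho| <$ `band_min`). The ratio is
defined on *counts*, not rates: with 3,393 effect against 1,320
comparison voxels in WD, a rate ratio $\beta/\alpha$ could never reach
4 at large $\alpha$ (since $\beta \le 1$), whereas the count ratio
crosses 4 at $\alpha \approx 0.36$ for $n = 30$ — a threshold two
orders of magnitude more liberal than convention, which is the point of
the exercise. The ratio is continuous and strictly decreasing in
$\alpha$, so plain bisection on $(10^{-6}, 0.999)$ finds the unique
root; analytic mode sums voxel-wise Fisher powers, simulation mode
estimates the same expectations from freshly simulated cohorts, and the
two agree within Monte-Carlo error (a property under test).

## Numerical and design choices

* **Seeds.** Every stochastic entry point takes an explicit integer
  seed and restores the caller's RNG state. Experiments derive
  per-repetition seeds as `master_seed + size_index * 1e5 + rep`, so a
  configuration reproduces every output byte for byte.
* **Exact band counts.** "About 72%" and "3.8%" become
  `round(fraction × n_voxels)` so structural tests can assert integers.
* **Degenerate inputs.** Empty truth sets raise errors (an undefined
  metric, not a zero); two empty maps give Dice `NA`; an empty
  significant set gives mean significant `|r|` `NA`. `NA` is a value
  with a reported count, never silently dropped into means.
* **Quadrature edge.** The exact-power integrand vanishes at
  $r = \pm 1$ for $n > 4$; `integrate()` handles the closed interval
  directly. For $\rho = 0$ the size $\alpha$ is returned exactly.
* **Problem sizes.** The shipped test-and-reproduction configurations
  use one full cohort of n = 10,000 per scenario, 500 repetitions for
  single-size power estimates and 200 per size for curve and
  at-least-one summaries (Monte-Carlo SE below half a percentage point
  for power means), and scaled 20 × 20 grids for properties that are
  grid-size-invariant, such as the exactness of the designed
  correlations at n = 50,000 and the analytic-vs-simulation agreement
  of the balancing search. These sizes are the package's chosen
  trade-off between precision and desk-scale runtime.

## Known limitations

* At-least-one power is reported against the designed truth; in WD,
  where every voxel is a true effect, it reduces to "any voxel
  significant". With smoothed noise the effective number of independent
  tests is far below 4,713, so at the smallest sample sizes a fraction
  of repetitions below about 1% can yield zero detections; at-least-one
  power is therefore "100%" only to Monte-Carlo resolution.
* The uncorrected default threshold is deliberate (it mirrors common
  practice and maximizes the average/at-least-one contrast), not a
  recommendation. FDR thresholding is available; FWE, cluster-extent,
  TFCE, and permutation schemes are out of scope.
* The simulation is 2D and single-slice; absolute voxel counts scale
  differently in 3D, though the qualitative power/inflation/replication
  relationships do not depend on dimensionality.
* Dice is computed on binarized maps only; no cluster-level or
  weighted overlap variants.
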