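mask6 <- make_mask(c(2, 3), 6)

sig_of <- function(v) sig_from_logical(v, mask6)

truth_of <- function(v) {
  structure(list(mode = "designed_any", true_mask = v, band_min = NULL,
                 n_true = sum(v)), class = "truth_set")
}

test_that("average power counts detected true voxels", {
  tr <- truth_of(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(average_power(sig_of(tr$true_mask), tr), 1)
  expect_equal(average_power(sig_of(rep(FALSE, 6)), tr), 0)
  expect_equal(average_power(sig_of(c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)), tr),
               0.25)
  expect_error(average_power(sig_of(rep(TRUE, 6)), truth_of(rep(FALSE, 6))),
               "empty")
})

test_that("at-least-one power flags any true detection", {
  tr <- truth_of(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(at_least_one(sig_of(rep(FALSE, 6)), tr))
  expect_true(at_least_one(sig_of(c(TRUE, rep(FALSE, 5))), tr))
  expect_true(at_least_one(sig_of(rep(TRUE, 6)), tr))
  # false positives alone do not count
  expect_false(at_least_one(sig_of(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)), tr))
})

test_that("avg_power > 0 implies at_least_one", {
  set.seed(4)
  tr <- truth_of(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  for (i in 1:50) {
    s <- sig_of(runif(6) < 0.4)
    if (average_power(s, tr) > 0) expect_true(at_least_one(s, tr))
  }
})

test_that("mean significant effect uses |r| and is NA when empty", {
  sm <- statmap_from_p(c(0.001, 0.5, 0.5, 0.5, 0.5, 0.5), mask = mask6)
  sm$r[1] <- -0.5
  expect_equal(mean_significant_effect(sm, sig_of(c(TRUE, rep(FALSE, 5)))), 0.5)
  expect_true(is.na(mean_significant_effect(sm, sig_of(rep(FALSE, 6)))))
})

test_that("significant effects are structurally inflated above critical r", {
  f <- make_effect_field(small_wd_spec())
  co <- generate_cohort(f, 2000, seed = 31)
  spec <- threshold_spec("uncorrected", 0.01)
  rc <- critical_r(0.01, 30)
  found <- 0
  for (i in 1:30) {
    sm <- correlate(co, draw_subsample(co, 30, seed = i))
    sig <- threshold(sm, spec)
    m <- mean_significant_effect(sm, sig)
    if (!is.na(m)) {
      found <- found + 1
      expect_gte(m, rc)
      # hence far above the largest designed WD effect of 0.14
      expect_gt(m, 0.14)
    }
  }
  expect_gt(found, 0)
})

test_that("percent significant is a straight voxel percentage", {
  expect_equal(percent_significant(sig_of(rep(FALSE, 6))), 0)
  expect_equal(percent_significant(sig_of(rep(TRUE, 6))), 100)
  expect_equal(percent_significant(sig_of(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))), 50)
})

test_that("dice is symmetric, 1 on identity, NA on two empty maps", {
  a <- sig_of(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  b <- sig_of(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  d <- sig_of(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, b), 2 * 2 / 6)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, d), 0)
  expect_true(is.na(dice(sig_of(rep(FALSE, 6)), sig_of(rep(FALSE, 6)))))
  other <- sig_from_logical(rep(TRUE, 4), make_mask(c(2, 2), 4))
  expect_error(dice(a, other), "different masks")
})

test_that("selectivity index is the complement of out-of-ROI spread", {
  roi <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(selectivity_index(sig_of(c(TRUE, TRUE, rep(FALSE, 4))), roi), 1)
  expect_equal(selectivity_index(sig_of(rep(TRUE, 6)), roi), 0)
  # 2 of 4 outside-ROI voxels significant -> 0.5
  expect_equal(selectivity_index(sig_of(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)), roi),
               0.5)
  expect_error(selectivity_index(sig_of(rep(TRUE, 6)), rep(TRUE, 6)), "strict subset")
  expect_error(selectivity_index(sig_of(rep(TRUE, 6)), rep(FALSE, 6)), "strict subset")
})

test_that("truth set modes partition the field as documented", {
  mask <- small_mask()
  rho <- rep(0, mask$n_voxels)
  rho[1:40] <- seq(0.02, 0.8, length.out = 40)
  f <- synthetic_field(rho, mask)
  expect_identical(truth_set(f, "designed_any")$true_mask, rho != 0)
  tb <- truth_set(f, "designed_band", band_min = 0.5)
  expect_identical(tb$true_mask, abs(rho) >= 0.5)
  full_sig <- sig_from_logical(rho > 0.3, mask)
  expect_identical(truth_set(f, "fullsample_sig", full_sig = full_sig)$true_mask,
                   rho > 0.3)
  expect_error(truth_set(f, "fullsample_sig"), "full_sig")
})

test_that("null scenario: no true effects, and spread near alpha", {
  mask <- small_mask()
  f0 <- synthetic_field(rep(0, mask$n_voxels), mask)
  tr <- truth_set(f0, "designed_any")
  expect_identical(tr$n_true, 0L)
  spec <- threshold_spec("uncorrected", 0.05)
  set.seed(99)
  pct <- replicate(200, {
    co <- generate_cohort(f0, 30, seed = sample.int(1e6, 1))
    percent_significant(threshold(correlate(co), spec))
  })
  expect_error(average_power(sig_from_logical(rep(TRUE, mask$n_voxels), mask), tr),
               "empty")
  expect_equal(mean(pct), 5, tolerance = 0.25)
})
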