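test_that("voxelwise Pearson r matches a sum-of-products oracle", {
  y <- c(1, 2, 3, 4, 5)
  x <- cbind(c(2, 1, 4, 3, 5), c(5, 4, 3, 2, 1), rnorm(5))
  co <- synthetic_cohort(y, x)
  sm <- correlate(co)
  expect_equal(sm$r[1], 0.8)
  expect_equal(sm$r[2], -1)
  for (v in 1:3) expect_equal(sm$r[v], pearson_oracle(y, x[, v]))
  # t statistic and p-value are consistent with the t(n-2) reference
  ok <- abs(sm$r) < 1
  expect_equal(sm$t[ok], sm$r[ok] * sqrt((5 - 2) / (1 - sm$r[ok]^2)))
  expect_equal(sm$p[ok], 2 * pt(-abs(sm$t[ok]), df = 3))
  # agreement with cor.test
  ct <- cor.test(x[, 3], y)
  expect_equal(sm$r[3], unname(ct$estimate))
  expect_equal(sm$p[3], ct$p.value)
})

test_that("perfect and null correlations sit at the p-value extremes", {
  y <- rnorm(20)
  co <- synthetic_cohort(y, cbind(y, -y))
  sm <- correlate(co)
  expect_equal(sm$r, c(1, -1))
  expect_equal(sm$p, c(0, 0))
  # r = 0 exactly -> p = 1
  y2 <- c(-2, -1, 0, 1, 2)
  sm2 <- correlate(synthetic_cohort(y2, cbind(c(1, -1, 0, -1, 1))))
  expect_equal(sm2$r[1], 0)
  expect_equal(sm2$p[1], 1)
})

test_that("constant activation columns degrade gracefully", {
  y <- rnorm(10)
  co <- synthetic_cohort(y, cbind(rnorm(10), rep(3, 10)))
  expect_warning(sm <- correlate(co), "constant")
  expect_equal(sm$r[2], 0)
  expect_equal(sm$p[2], 1)
  expect_false(is.na(sm$r[1]))
})

test_that("critical r inverts the two-sided p-value", {
  expect_equal(critical_r(0.01, 30), 0.4629, tolerance = 1e-4)
  # round trip: p(critical_r(alpha, n), n) == alpha
  for (alpha in c(0.05, 0.01, 0.001)) {
    for (n in c(5, 30, 150)) {
      rc <- critical_r(alpha, n)
      t <- rc * sqrt((n - 2) / (1 - rc^2))
      expect_equal(2 * pt(-t, df = n - 2), alpha, tolerance = 1e-10)
    }
  }
  # alpha -> 1 limit: threshold vanishes
  expect_lt(critical_r(0.9999, 30), 0.001)
  expect_error(critical_r(0, 30), "range")
  expect_error(critical_r(0.05, 3), "at least")
})

test_that("BH step-up rejects the hand-worked set", {
  sm <- statmap_from_p(c(0.001, 0.02, 0.03, 0.2))
  sig <- threshold(sm, threshold_spec("fdr_bh", 0.05))
  expect_identical(sum(sig$sig), 3L)
  expect_identical(which(!sig$sig), 4L)
  # all p below alpha -> everything significant, uncorrected
  sm2 <- statmap_from_p(rep(0.009, 5))
  expect_true(all(threshold(sm2, threshold_spec("uncorrected", 0.01))$sig))
})

test_that("uncorrected thresholding equals critical-r masking", {
  set.seed(3)
  f <- make_effect_field(small_wd_spec())
  co <- generate_cohort(f, 40, seed = 12)
  sm <- correlate(co)
  for (alpha in c(0.05, 0.01)) {
    sig <- threshold(sm, threshold_spec("uncorrected", alpha))
    expect_identical(sig$sig, abs(sm$r) >= critical_r(alpha, sm$n))
  }
})

test_that("p-values are uniform under the global null", {
  mask <- make_mask(c(10, 10), 60)
  f0 <- synthetic_field(rep(0, mask$n_voxels), mask)
  p <- numeric(500)
  rate <- numeric(500)
  for (i in seq_len(500)) {
    sm <- correlate(generate_cohort(f0, 30, seed = 1000 + i))
    p[i] <- sm$p[17] # one fixed voxel across repetitions
    rate[i] <- mean(sm$p < 0.05)
  }
  expect_gt(ks.test(p, "punif")$p.value, 1e-3)
  # rejection rate at alpha on designed-null voxels is alpha, up to
  # Monte-Carlo error (voxels within a map are spatially correlated)
  expect_equal(mean(rate), 0.05, tolerance = 0.2)
})
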