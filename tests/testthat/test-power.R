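test_that("exact power reproduces frozen reference values", {
  # medium effect, small sample, strict threshold: the calibration point
  expect_equal(power_correlation(0.3, 30, 0.001, method = "exact"),
               0.04160, tolerance = 1e-3)
  # null gives exactly the test size
  expect_equal(power_correlation(0, 30, 0.05, method = "exact"), 0.05)
  # the exact sampling density integrates to 1
  expect_equal(
    integrate(voxelpower:::r_sampling_density, -1, 1, rho = 0.3,
              n = 30)$value, 1, tolerance = 1e-7)
})

test_that("Fisher approximation brackets the exact value as computed", {
  expect_equal(power_correlation(0.3, 30, 0.001, method = "fisher",
                                 bias_correction = FALSE),
               0.03931, tolerance = 1e-3)
  expect_equal(power_correlation(0.3, 30, 0.001, method = "fisher",
                                 bias_correction = TRUE),
               0.04165, tolerance = 1e-3)
  # vectorized over rho
  pw <- power_correlation(c(0.1, 0.3, 0.5), 30, 0.05, method = "fisher")
  expect_length(pw, 3)
  expect_true(all(diff(pw) > 0))
})

test_that("exact power agrees with a Monte-Carlo oracle across the grid", {
  draws <- 100000
  for (rho in c(0.1, 0.3, 0.7)) {
    for (n in c(10, 30, 150)) {
      for (alpha in c(0.05, 0.01, 0.001)) {
        exact <- power_correlation(rho, n, alpha, method = "exact")
        mc <- mc_power_oracle(rho, n, alpha, draws,
                              seed = round(1000 * rho) + n)
        tol <- 0.003 + 4 * sqrt(max(mc * (1 - mc), 1e-5) / draws)
        expect_equal(exact, mc, tolerance = max(tol / max(exact, 1e-8), 1e-8),
                     label = sprintf("exact(rho=%g,n=%d,a=%g)", rho, n, alpha),
                     expected.label = "MC oracle")
      }
    }
  }
})

test_that("power is strictly increasing in rho, n, and alpha", {
  for (method in c("exact", "fisher")) {
    expect_true(all(diff(power_correlation(c(0.1, 0.3, 0.5, 0.7), 30,
                                           0.01, method)) > 0))
    pw_n <- sapply(c(10, 30, 80, 150),
                   function(n) power_correlation(0.3, n, 0.01, method))
    expect_true(all(diff(pw_n) > 0))
    pw_a <- sapply(c(0.001, 0.01, 0.05, 0.2),
                   function(a) power_correlation(0.3, 30, a, method))
    expect_true(all(diff(pw_a) > 0))
  }
  expect_error(power_correlation(1, 30, 0.05), "rho")
})

test_that("Fisher-z confidence intervals match the closed form", {
  ci <- ci_correlation(0, 100, 0.95)
  expect_equal(unname(ci), c(-1, 1) * tanh(qnorm(0.975) / sqrt(97)))
  expect_equal(unname(ci[2]), 0.1964, tolerance = 1e-3)
  # large n: narrow interval around r
  ci2 <- ci_correlation(0.3, 10000, 0.95)
  expect_lt(ci2[2] - ci2[1], 0.04)
  expect_true(ci2[1] < 0.3 && 0.3 < ci2[2])
  # level -> 0: interval collapses onto r
  ci3 <- ci_correlation(0.3, 30, 1e-10)
  expect_equal(unname(ci3), c(0.3, 0.3), tolerance = 1e-6)
  expect_warning(ci4 <- ci_correlation(1, 30), "degenerates")
  expect_equal(unname(ci4), c(1, 1))
})

test_that("empirical CI coverage is near nominal", {
  set.seed(21)
  rho <- 0.3; n <- 50
  hits <- 0
  for (i in 1:1000) {
    y <- rnorm(n)
    x <- rho * y + sqrt(1 - rho^2) * rnorm(n)
    ci <- ci_correlation(cor(x, y), n, 0.95)
    hits <- hits + (ci[1] <= rho && rho <= ci[2])
  }
  expect_equal(hits / 1000, 0.95, tolerance = 0.03)
})
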