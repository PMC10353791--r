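test_that("independent sampling has the right support, mean and seeding", {
  m <- sample_independent(4, 2e4, seed = 3)
  expect_true(all(m >= 0 & m <= 2))
  expect_lt(max(abs(colMeans(m) - 1)), 3 * sqrt(1 / 3 / 2e4))
  expect_identical(sample_independent(4, 2e4, seed = 3), m)
  expect_false(identical(sample_independent(4, 2e4, seed = 4), m))
})

test_that("valid_fraction applies a strict tolerance on the row-mean deviation", {
  m <- sample_independent(3, 1000, seed = 1)
  expect_equal(valid_fraction(m, tol = Inf), 1)
  # boundary is strict: a deviation exactly equal to tol is invalid
  expect_equal(valid_fraction(matrix(0.5, 1, 2), target = 0, tol = 0.5), 0)
  expect_equal(valid_fraction(matrix(0.5, 1, 2), target = 0,
                              tol = 0.5 + 1e-9), 1)
})

test_that("the Irwin-Hall oracle matches closed forms and Monte Carlo", {
  expect_equal(analytic_valid_fraction(1), 0.015)
  expect_equal(analytic_valid_fraction(2), 0.029775)
  # n = 8 against Monte Carlo at 1e6 samples
  p8 <- analytic_valid_fraction(8)
  mc8 <- valid_fraction(sample_independent(8, 1e6, seed = 13))
  expect_lt(abs(p8 - mc8), 3 * sqrt(p8 * (1 - p8) / 1e6))
  # exact-to-Edgeworth handover stays smooth and monotone
  ps <- vapply(22:30, analytic_valid_fraction, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_lt(max(abs(diff(ps))) , 5e-3)
})

test_that("copula samples have uniform marginals and the predicted correlation", {
  m0 <- sample_copula(5, 0, 2e5, seed = 2)
  r0 <- stats::cor(m0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 3 / sqrt(2e5))
  m5 <- sample_copula(5, 0.5, 2e5, seed = 2)
  r5 <- stats::cor(m5)
  target <- 6 / pi * asin(0.25)
  se <- (1 - target^2) / sqrt(2e5)
  expect_lt(abs(mean(r5[upper.tri(r5)]) - target), 3 * se)
  # marginal uniformity on [0, 2] across seeded runs
  rejections <- sum(vapply(1:20, function(s) {
    m <- sample_copula(3, 0.4, 5e3, seed = s)
    stats::ks.test(m[, 1] / 2, "punif")$p.value < 0.01
  }, logical(1)))
  expect_lte(rejections, 1)
  # infeasible negative pairwise correlation is rejected with the bound
  expect_error(sample_copula(5, -0.5, 10), "-1/\\(n-1\\)|positive semidefinite")
})

test_that("the distributed sampler fills the largest gap first", {
  m1 <- sample_distributed(1, 5e3, seed = 6)
  expect_gt(stats::ks.test(m1[, 1] / 2, "punif")$p.value, 0.001)
  # second draw always falls in the larger side interval
  m2 <- sample_distributed(2, 5e3, seed = 7)
  larger_left <- m2[, 1] >= 2 - m2[, 1]
  expect_true(all(m2[larger_left, 2] < m2[larger_left, 1]))
  expect_true(all(m2[!larger_left, 2] > m2[!larger_left, 1]))
  # row means concentrate harder than independent sampling at n = 5
  vd <- stats::var(rowMeans(sample_distributed(5, 2e4, seed = 8)))
  vi <- 1 / 3 / 5
  expect_lt(vd, vi * 0.8)
})

test_that("the sigmoid and interaction transform follow their definitions", {
  expect_equal(toy_sigmoid(0), 0)
  xs <- c(-3, -1, 0, 1, 3)
  expect_equal(toy_sigmoid(xs), tanh(xs / 2), tolerance = 1e-12)
  cfgs <- lapply(0:2, function(o) nonlinear_config(5, o, seed = 11))
  for (cfg in cfgs) {
    expect_equal(colSums(cfg$M), rep(1, 5), tolerance = 1e-12)
    expect_equal(colSums(cfg$Mhat), rep(1, 5), tolerance = 1e-12)
  }
  # order 0 on a constant row applies the sigmoid elementwise
  u <- rep(1.3, 5)
  expect_equal(nonlinear_transform(u, cfgs[[1]]), toy_sigmoid(u))
  # outputs stay inside (-1, 1) for all orders
  m <- sample_independent(5, 500, seed = 12)
  for (cfg in cfgs) {
    v <- nonlinear_transform(m, cfg)
    expect_true(all(v > -1 & v < 1))
  }
  expect_error(nonlinear_transform(rep(1, 4), cfgs[[1]]), "dimension")
})

test_that("validity filtering induces negative output correlations", {
  m <- sample_independent(2, 3e5, seed = 21)
  valid <- m[abs(rowMeans(m) - 1) < 0.015, ]
  expect_gt(nrow(valid), 100)
  expect_lt(output_correlation_summary(valid), -0.5)
  # weaker pairwise correlation with more variables
  m3 <- sample_independent(3, 3e5, seed = 22)
  m8 <- sample_independent(8, 3e5, seed = 23)
  r3 <- output_correlation_summary(m3[abs(rowMeans(m3) - 1) < 0.015, ])
  r8 <- output_correlation_summary(m8[abs(rowMeans(m8) - 1) < 0.015, ])
  expect_lt(r3, 0)
  expect_lt(r8, 0)
  expect_lt(abs(r8), abs(r3))
  # no filtering, no correlation
  expect_lt(abs(output_correlation_summary(m)), 3 / sqrt(nrow(m)))
})

test_that("shrinking the sampling range raises the valid fraction", {
  tab <- range_shrink_experiment(1, half_widths = c(1, 0.5, 0.2, 0.1),
                                 n_samples = 5e4, seed = 31)
  expect_true(all(diff(tab$valid_fraction) > 0))
  se <- sqrt(0.15 * 0.85 / 5e4)
  expect_lt(abs(tab$valid_fraction[tab$half_width == 0.1] - 0.15), 3 * se)
  # a range inside the tolerance window is always valid
  tiny <- range_shrink_experiment(3, half_widths = 0.007, n_samples = 1000,
                                  seed = 32)
  expect_equal(tiny$valid_fraction, 1)
})

test_that("the LLN curve estimator is unbiased against the analytic oracle", {
  hits <- 0L
  for (s in 1:20) {
    cur <- toy_lln_curve(c(2, 5, 8), n_samples = 2e4, seed = s)
    ok <- abs(cur$valid_fraction - cur$analytic) <= 3 * cur$se
    hits <- hits + sum(ok)
  }
  expect_gte(hits, 0.95 * 20 * 3 - 3)  # ~3 SE coverage over 60 cells
})
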