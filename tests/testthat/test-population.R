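test_that("population sampling respects range, frozen keys and seeding", {
  cfg <- baselines$gc5
  m <- sample_population(cfg, 300, seed = 5)
  base <- cfg$conductance_table
  for (k in free_parameters(cfg)) {
    expect_true(all(m[, k] >= 0 & m[, k] <= 2 * base[k]))
  }
  for (k in cfg$frozen_parameters) {
    expect_true(all(m[, k] == base[k]))
  }
  expect_identical(sample_population(cfg, 300, seed = 5), m)
  expect_false(identical(sample_population(cfg, 300, seed = 6), m))
  # a zero baseline density cannot span a 0-2x range
  cfg0 <- apply_parameters(cfg, c("BK@soma" = 0))
  expect_error(sample_population(cfg0, 10), "degenerate")
})

test_that("classification reduces to the flag fraction with Wilson interval", {
  m <- sample_independent(3, 50, seed = 1)
  always <- classify_population(m, function(row) 0)
  expect_equal(always$valid_fraction, 1)
  never <- classify_population(m, function(row) 6)
  expect_equal(never$valid_fraction, 0)
  expect_error(classify_population(m[0, , drop = FALSE], function(row) 0),
               "empty")
  expect_true(all(always$ci >= 0 & always$ci <= 1))
})

test_that("the valid-fraction estimator agrees with the Irwin-Hall oracle", {
  n <- 2e5
  m <- sample_independent(5, n, seed = 77)
  res <- classify_population(m, toy_rule_evaluator())
  p <- analytic_valid_fraction(5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(res$valid_fraction - p), 3 * se)
})

test_that("range sweep fractions behave as the nesting argument predicts", {
  # half-width zero: every sample is the (valid) baseline
  base1 <- c(x = 1)
  r0 <- range_sweep(base1, 0, n_per = 50, evaluator = toy_rule_evaluator(),
                    seed = 2)
  expect_equal(r0$valid_fraction, 1)
  # one variable, w = 0.1: window 0.03 over range width 0.2
  r1 <- range_sweep(base1, 0.1, n_per = 5e4,
                    evaluator = toy_rule_evaluator(), seed = 3)
  se <- sqrt(0.15 * 0.85 / 5e4)
  expect_lt(abs(r1$valid_fraction - 0.15), 3 * se)
  # fractions non-increasing as the range widens (5 variables)
  base5 <- stats::setNames(rep(1, 5), paste0("x", 1:5))
  rs <- range_sweep(base5, c(0.1, 0.3, 0.6, 1), n_per = 5e4,
                    evaluator = toy_rule_evaluator(), seed = 4)
  expect_true(all(diff(rs$valid_fraction) < 0))
  expect_error(range_sweep(base1, 1.5, evaluator = toy_rule_evaluator()),
               "half_widths")
})

test_that("pairwise correlations flag real structure and skip degenerate columns", {
  set.seed(8)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- cbind(x, d = x[, "a"])          # duplicated column
  x <- cbind(x, e = rep(2, 200))       # constant column
  pc <- pairwise_correlations(x)
  expect_equal(pc$r["a", "d"], 1)
  expect_true(pc$flag["a", "d"])
  expect_true(is.na(pc$r["a", "e"]))
  expect_false(pc$flag["a", "e"])
  expect_error(pairwise_correlations(x[1:2, ]), "at least 3")
})

test_that("null data produce few significant pairwise correlations", {
  worst_r <- 0
  flags <- 0L
  pairs <- 0L
  for (rep in 1:30) {
    m <- sample_independent(5, 1e4, seed = 1000 + rep)
    pc <- pairwise_correlations(m)
    ut <- upper.tri(pc$r)
    worst_r <- max(worst_r, max(abs(pc$r[ut])))
    flags <- flags + sum(pc$flag[ut])
    pairs <- pairs + sum(ut)
  }
  expect_lt(worst_r, 0.05)
  expect_lt(flags / pairs, 0.1)  # nominal 1% at alpha = 0.01
})

test_that("random walks stop at invalidity and use bounded multiplicative steps", {
  start <- c(x = 1, y = 1)
  expect_identical(random_walk(start, function(r) 0, max_steps = 17, seed = 1),
                   17)
  only_start <- function(r) if (all(r == start)) 0 else 6
  expect_identical(random_walk(start, only_start, max_steps = 50, seed = 1), 0L)
  expect_error(random_walk(start, function(r) 6), "valid point")
  # per-step factors stay within [0.95, 1.05]
  visited <- list()
  rec <- function(r) {
    visited[[length(visited) + 1L]] <<- r
    0
  }
  random_walk(start, rec, max_steps = 40, seed = 9)
  path <- do.call(rbind, visited)
  ratios <- path[-1, ] / path[-nrow(path), ]
  expect_true(all(ratios >= 0.95 & ratios <= 1.05))
  # seeded reproducibility
  expect_identical(random_walk(c(x = 1), toy_rule_evaluator(0.2),
                               max_steps = 100, seed = 3),
                   random_walk(c(x = 1), toy_rule_evaluator(0.2),
                               max_steps = 100, seed = 3))
})

test_that("walk ensembles conserve counts and report the arithmetic mean", {
  ev <- toy_rule_evaluator(0.2)
  w <- walk_ensemble(c(x = 1), ev, reps = 60, max_steps = 100, seed = 12)
  expect_identical(sum(w$histogram$count), 60L)
  expect_equal(w$mean_steps, mean(w$steps))
  expect_true(all(w$histogram$bin_lo %% 4 == 0))
  w2 <- walk_ensemble(c(x = 1), ev, reps = 60, max_steps = 100, seed = 12)
  expect_identical(w$steps, w2$steps)
})

test_that("walk survival is monotone in the validity tolerance", {
  # P proportional to the distance from the target: threshold 3 is looser
  ev <- function(r) 40 * abs(mean(r) - 1)
  s2 <- vapply(1:40, function(i)
    random_walk(c(x = 1, y = 1), ev, max_steps = 200, seed = i, threshold = 2),
    numeric(1))
  s3 <- vapply(1:40, function(i)
    random_walk(c(x = 1, y = 1), ev, max_steps = 200, seed = i, threshold = 3),
    numeric(1))
  expect_true(all(s3 >= s2))
  expect_gte(mean(s3), mean(s2))
})

test_that("isoform expansion alternates parents and refines three candidates", {
  base5 <- baselines$gc5
  r0 <- expand_isoforms(base5, 0, solver = pop_solver, seed = 1)
  expect_identical(vapply(r0$config$channels, `[[`, character(1), "name"),
                   vapply(base5$channels, `[[`, character(1), "name"))
  expect_equal(r0$P, 0)
  # k = 2: one BK isoform (2 regions) + one Cav22 isoform (3 regions)
  sc <- search_config(max_outer_iterations = 1, max_line_evals = 3)
  r2 <- expand_isoforms(base5, 2, initial_sample_size = 4, search = sc,
                        solver = pop_solver, seed = 5)
  expect_identical(length(r2$config$conductance_table), 9L + 2L + 3L)
  expect_identical(length(r2$refined), 3L)
  names2 <- vapply(r2$config$channels, `[[`, character(1), "name")
  expect_true(all(c("BK_iso1", "Cav22_iso2") %in% names2))
  # density splitting conserves the family total at the default point
  tab2 <- r2$config
  expect_identical(length(free_parameters(tab2)), 7L + 5L)
})

test_that("pairwise hyperplane interpolation uses nine convex combinations", {
  a <- c(x = 1, y = 2)
  b <- c(x = 3, y = 0.5)
  f <- counting(function(v) 0)
  h <- hyperplane_pair(a, b, f)
  expect_identical(attr(f, "count")(), 9L)
  expect_true(h$connected)
  expect_equal(h$weights, seq(0.1, 0.9, by = 0.1))
  # interpolant coordinates lie between the endpoints
  for (w in h$weights) {
    v <- w * a + (1 - w) * b
    expect_true(all(v >= pmin(a, b) & v <= pmax(a, b)))
  }
  # degenerate pair: connected iff the shared point is valid
  expect_true(hyperplane_pair(a, a, function(v) 1.9)$connected)
  expect_false(hyperplane_pair(a, a, function(v) 2)$connected)
  expect_error(hyperplane_pair(a, c(x = 1), function(v) 0), "layout")
})

test_that("triplet hyperplane grids mask negative combinations and hit vertices", {
  set.seed(14)
  a <- c(p = 1, q = 0.2, r = 1.5)
  b <- c(p = 0.3, q = 1.1, r = 0.4)
  c3 <- c(p = 2, q = 0.6, r = 0.9)
  ev <- function(v) sum(v)
  h <- hyperplane_triplet(a, b, c3, ev)
  g <- h$grid
  reg <- g[!g$vertex, ]
  expect_identical(length(unique(reg$w1)), 101L)
  expect_identical(length(unique(reg$w2)), 101L)
  # vertex (1, 0) reproduces vector A exactly
  va <- g[g$w1 == 1 & g$w2 == 0, ]
  expect_equal(va$P, sum(a))
  vb <- g[g$w1 == 0 & g$w2 == 1, ]
  expect_equal(vb$P, sum(b))
  vc <- g[g$w1 == 0 & g$w2 == 0, ]
  expect_equal(vc$P, sum(c3))
  # masked points have at least one negative coordinate, retained none
  some <- g[sample(nrow(g), 400), ]
  for (i in seq_len(nrow(some))) {
    v <- some$w1[i] * a + some$w2[i] * b + (1 - some$w1[i] - some$w2[i]) * c3
    if (some$masked[i]) expect_true(any(v < 0)) else expect_true(all(v >= 0))
  }
  expect_true(any(g$masked))
  expect_error(hyperplane_triplet(a, b, c3[1:2], ev), "layout")
})
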