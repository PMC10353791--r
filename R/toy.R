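#' Independent uniform toy-model sample
#'
#' Each of `n_vars` variables is drawn i.i.d. uniformly on `range`
#' (default `[0, 2]`), mimicking conductances sampled around a functional
#' set point at 1.
#'
#' @param n_vars number of variables per row.
#' @param n_samples number of rows.
#' @param range sampling interval (default `c(0, 2)`).
#' @param seed RNG seed.
#' @return `n_samples x n_vars` matrix.
#' @export
sample_independent <- function(n_vars, n_samples, range = c(0, 2), seed = 1L) {
  stopifnot(n_vars >= 1, n_samples >= 1, range[1] < range[2])
  withr::with_seed(seed, matrix(stats::runif(n_samples * n_vars, range[1], range[2]),
                                nrow = n_samples))
}

#' Fraction of valid toy models
#'
#' A row is valid iff the absolute deviation of its mean from the target is
#' strictly below the tolerance.
#'
#' @param m sample matrix (rows = models).
#' @param target target value (default 1).
#' @param tol tolerance (default 0.015, strict).
#' @return Fraction in `[0, 1]`.
#' @export
valid_fraction <- function(m, target = 1, tol = 0.015) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  stopifnot(nrow(m) >= 1)
  mean(abs(rowMeans(m) - target) < tol)
}

# Irwin-Hall CDF: P(sum of n iid U(0,1) <= x), exact alternating sum.
irwin_hall_cdf <- function(x, n) {
  if (x <= 0) return(0)
  if (x >= n) return(1)
  k <- 0:floor(x)
  sum((-1)^k * choose(n, k) * (x - k)^n) / factorial(n)
}

#' Exact probability that a uniform toy model is valid
#'
#' Probability that the mean of `n_vars` i.i.d. uniforms on `[0, 2]` lies
#' strictly within `tol` of 1, via the Irwin-Hall distribution. The exact
#' alternating-sum form is used up to `n_vars = 25`; beyond that it loses
#' too many digits to cancellation in double precision, and an Edgeworth
#' (kurtosis-corrected normal) approximation is used instead, whose error
#' (O(n^-2), and the skewness term vanishes for a symmetric interval) is far
#' below Monte Carlo resolution at any practical sample size.
#'
#' @param n_vars number of variables (>= 1).
#' @param tol tolerance (default 0.015).
#' @return Probability.
#' @export
analytic_valid_fraction <- function(n_vars, tol = 0.015) {
  stopifnot(n_vars >= 1, tol > 0)
  # mean of n U(0,2) within tol of 1  <=>  sum of n U(0,1) within n*tol/2 of n/2
  delta <- n_vars * tol / 2
  if (n_vars <= 25) {
    irwin_hall_cdf(n_vars / 2 + delta, n_vars) -
      irwin_hall_cdf(n_vars / 2 - delta, n_vars)
  } else {
    sigma <- sqrt(n_vars / 12)
    z <- delta / sigma
    gamma2 <- -6 / (5 * n_vars)  # excess kurtosis of the sum
    base <- 2 * stats::pnorm(z) - 1
    corr <- -2 * stats::dnorm(z) * gamma2 / 24 * (z^3 - 3 * z)
    base + corr
  }
}

#' Gaussian-copula toy-model sample with uniform marginals
#'
#' Imposes an equicorrelated latent Gaussian structure (pairwise latent
#' correlation `rho`) on variables with uniform marginals on `[0, 2]`:
#' standard normal deviates are correlated through the Cholesky factor of
#' `R` (`R[i,j] = rho`, `R[i,i] = 1`), mapped to `[0, 1]` by the normal CDF
#' and scaled by 2.
#'
#' @param n_vars number of variables.
#' @param rho pairwise latent correlation; must satisfy
#'   `rho >= -1/(n_vars - 1)` for positive semidefiniteness.
#' @param n_samples number of rows.
#' @param seed RNG seed.
#' @return `n_samples x n_vars` matrix with U(0, 2) marginals.
#' @export
sample_copula <- function(n_vars, rho, n_samples, seed = 1L) {
  stopifnot(n_vars >= 1, n_samples >= 1)
  R <- matrix(rho, n_vars, n_vars)
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch))
    stop("correlation matrix is not positive semidefinite: pairwise rho must ",
         "be >= -1/(n-1) = ", signif(-1 / (n_vars - 1), 4),
         " for n = ", n_vars, " variables")
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * n_vars), nrow = n_samples) %*% ch
  })
  2 * stats::pnorm(z)
}

#' 'Distributed' toy-model sample via largest-gap insertion
#'
#' Generates each row sequentially: the first variable is uniform on
#' `[0, 2]`; every subsequent variable is drawn uniformly from the largest
#' gap between the ordered existing variables, where the boundary gaps
#' `[0, min]` and `[max, 2]` count as gaps. Ties between equal-length gaps
#' are broken towards the lowest left endpoint. The resulting rows are more
#' evenly spread than independent draws, so their means concentrate harder
#' around 1.
#'
#' @param n_vars variables per row.
#' @param n_samples rows.
#' @param seed RNG seed.
#' @return `n_samples x n_vars` matrix.
#' @export
sample_distributed <- function(n_vars, n_samples, seed = 1L) {
  stopifnot(n_vars >= 1, n_samples >= 1)
  withr::with_seed(seed, {
    out <- matrix(NA_real_, n_samples, n_vars)
    for (r in seq_len(n_samples)) {
      xs <- stats::runif(1, 0, 2)
      while (length(xs) < n_vars) {
        pts <- c(0, sort(xs), 2)
        gaps <- diff(pts)
        g <- which.max(gaps)  # which.max takes the first (lowest) maximum
        xs <- c(xs, stats::runif(1, pts[g], pts[g + 1]))
      }
      out[r, ] <- xs
    }
    out
  })
}

#' Nonlinear-interaction configuration for the toy model
#'
#' Draws the interaction matrices `M` and `Mhat` (`n x n`, entries uniform
#' on `[-1, 1]`, columns normalized to sum to 1, i.e. left-stochastic).
#' Columns whose raw sum is too close to zero are redrawn (with a message),
#' since normalization would explode.
#'
#' @param n_vars dimension.
#' @param order interaction order, 0, 1 or 2.
#' @param seed RNG seed.
#' @param min_colsum redraw threshold on the absolute raw column sum.
#' @return An object of class `nonlinear_config` with `M`, `Mhat`, `order`.
#' @export
nonlinear_config <- function(n_vars, order = 0L, seed = 1L, min_colsum = 0.1) {
  stopifnot(order %in% 0:2, n_vars >= 1)
  draw <- function() {
    m <- matrix(stats::runif(n_vars * n_vars, -1, 1), n_vars)
    for (j in seq_len(n_vars)) {
      tries <- 0L
      while (abs(sum(m[, j])) < min_colsum) {
        tries <- tries + 1L
        m[, j] <- stats::runif(n_vars, -1, 1)
      }
      if (tries > 0)
        message("resampled interaction-matrix column ", j,
                " (near-zero column sum, ", tries, " redraws)")
      m[, j] <- m[, j] / sum(m[, j])
    }
    m
  }
  withr::with_seed(seed, {
    M <- draw(); Mhat <- draw()
  })
  structure(list(M = M, Mhat = Mhat, order = as.integer(order)),
            class = "nonlinear_config")
}

#' Elementwise sigmoid of the nonlinear toy model
#'
#' `S(x) = -1 + 2 / (1 + exp(-x))`, identical to `tanh(x/2)`.
#'
#' @param x numeric vector.
#' @return Values in `(-1, 1)`.
#' @export
toy_sigmoid <- function(x) -1 + 2 / (1 + exp(-x))

#' Apply the nonlinear interaction transform to toy-model rows
#'
#' Order 0: `v0 = S(u)`; order 1: `v1 = S(M S(u))`; order 2:
#' `v2 = S(Mhat S(M S(u)))`.
#'
#' @param u numeric vector (one row) or matrix (rows transformed
#'   independently).
#' @param config a [nonlinear_config()] of matching dimension.
#' @return Transformed vector/matrix with entries in `(-1, 1)`.
#' @export
nonlinear_transform <- function(u, config) {
  stopifnot(inherits(config, "nonlinear_config"))
  vec <- is.null(dim(u))
  m <- if (vec) matrix(u, nrow = 1) else u
  if (ncol(m) != ncol(config$M)) stop("dimension mismatch with interaction matrices")
  v <- toy_sigmoid(m)
  if (config$order >= 1) v <- toy_sigmoid(v %*% t(config$M))
  if (config$order >= 2) v <- toy_sigmoid(v %*% t(config$Mhat))
  if (vec) drop(v) else v
}

#' Valid fraction of the nonlinear toy model
#'
#' The reference output is the transform of the all-ones row with the same
#' matrices; a row is valid iff the mean of its transformed output lies
#' strictly within `tol` of the mean of the reference output.
#'
#' @param u sample matrix (rows on `[0, 2]`).
#' @param config a [nonlinear_config()].
#' @param tol tolerance (default 0.015).
#' @return Fraction in `[0, 1]`.
#' @export
nonlinear_valid_fraction <- function(u, config, tol = 0.015) {
  v <- nonlinear_transform(u, config)
  ref <- nonlinear_transform(rep(1, ncol(u)), config)
  mean(abs(rowMeans(v) - mean(ref)) < tol)
}

#' Mean pairwise output correlation among valid rows
#'
#' Averages the upper-triangle Pearson correlations between variables over
#' the supplied (valid) rows; degenerate (constant) columns are excluded
#' from the average.
#'
#' @param valid_rows matrix with >= 3 rows and >= 2 columns.
#' @return Mean pairwise `r`.
#' @export
output_correlation_summary <- function(valid_rows) {
  stopifnot(nrow(valid_rows) >= 3, ncol(valid_rows) >= 2)
  r <- suppressWarnings(stats::cor(valid_rows))
  vals <- r[upper.tri(r)]
  mean(vals[is.finite(vals)])
}

#' Monte Carlo valid-fraction curve over the number of variables
#'
#' Estimates the valid fraction for each `n` in `n_values`. Two estimators
#' are available. `"indicator"` is the plain fraction of valid rows.
#' `"smoothed"` (default) is conditional Monte Carlo: for each row the
#' validity indicator is replaced by its exact conditional probability given
#' all but the last variable (the length of the admissible interval for the
#' last uniform divided by 2). Both are unbiased for the same quantity; the
#' smoothed estimator has substantially lower variance, which matters when
#' comparing adjacent `n`. Both use common random numbers across `n` (each
#' `n` uses the first columns of one shared uniform matrix), a standard
#' paired design that sharpens adjacent-`n` comparisons.
#'
#' @param n_values numbers of variables.
#' @param n_samples rows per estimate.
#' @param tol validity tolerance.
#' @param seed RNG seed.
#' @param method `"smoothed"` (conditional MC) or `"indicator"`.
#' @return Data frame `n_vars`, `valid_fraction`, `se`, `analytic`.
#' @export
toy_lln_curve <- function(n_values, n_samples = 1e5, tol = 0.015, seed = 1L,
                          method = c("smoothed", "indicator")) {
  method <- match.arg(method)
  n_values <- sort(n_values)
  nmax <- max(n_values)
  m <- sample_independent(nmax, n_samples, seed = seed)
  if (method == "indicator") {
    est <- lapply(n_values, function(n) {
      v <- abs(rowMeans(m[, seq_len(n), drop = FALSE]) - 1) < tol
      c(mean(v), stats::sd(v) / sqrt(n_samples))
    })
  } else {
    # prefix sums: s[, n] = sum of the first n - 1 variables
    s <- matrix(0, n_samples, nmax)
    if (nmax > 1)
      for (j in 2:nmax) s[, j] <- s[, j - 1] + m[, j - 1]
    est <- lapply(n_values, function(n) {
      lo <- pmax(0, n * (1 - tol) - s[, n])
      hi <- pmin(2, n * (1 + tol) - s[, n])
      h <- pmax(0, hi - lo) / 2
      c(mean(h), stats::sd(h) / sqrt(n_samples))
    })
  }
  est <- do.call(rbind, est)
  data.frame(n_vars = n_values, valid_fraction = est[, 1], se = est[, 2],
             analytic = vapply(n_values, analytic_valid_fraction, numeric(1),
                               tol = tol))
}

#' Valid fraction while shrinking the sampling range around the target
#'
#' For each combination of `n_vars` and half-width `w`, samples uniformly on
#' `[1 - w, 1 + w]` and reports the fraction of rows whose mean lies within
#' `tol` of 1.
#'
#' @param n_vars_values numbers of variables.
#' @param half_widths half-widths in `(0, 1]` (default 1.0 down to 0.1).
#' @param tol validity tolerance.
#' @param n_samples rows per cell.
#' @param seed RNG seed.
#' @return Tidy data frame `n_vars`, `half_width`, `valid_fraction`,
#'   `ci_lo`, `ci_hi`.
#' @export
range_shrink_experiment <- function(n_vars_values,
                                    half_widths = seq(1, 0.1, by = -0.1),
                                    tol = 0.015, n_samples = 1e5, seed = 1L) {
  stopifnot(all(half_widths > 0), all(half_widths <= 1))
  rows <- list()
  i <- 0L
  for (n in n_vars_values) for (w in half_widths) {
    i <- i + 1L
    m <- sample_independent(n, n_samples, range = c(1 - w, 1 + w),
                            seed = seed + i)
    fr <- valid_fraction(m, tol = tol)
    ci <- wilson_ci(round(fr * n_samples), n_samples)
    rows[[i]] <- data.frame(n_vars = n, half_width = w, valid_fraction = fr,
                            ci_lo = ci["lo"], ci_hi = ci["hi"],
                            row.names = NULL)
  }
  do.call(rbind, rows)
}
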