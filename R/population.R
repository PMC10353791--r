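#' Wilson score confidence interval for a proportion
#'
#' @param k successes, @param n trials, @param level confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Sample a population of conductance vectors around a baseline
#'
#' Each free density is drawn independently and uniformly from
#' `[lo, hi] x baseline`; frozen densities (`pas`, `Kir21` by default) are
#' copied unchanged into every row.
#'
#' @param config baseline [neuron_config()], or a named numeric vector of
#'   baseline values (then all entries are treated as free).
#' @param n_samples number of rows (default 20000).
#' @param fold_range `c(lo, hi)` in multiples of the baseline (default
#'   `c(0, 2)`).
#' @param seed RNG seed.
#' @return Numeric matrix `n_samples x n_parameters` with the conductance
#'   table's keys as column names (frozen columns constant).
#' @export
sample_population <- function(config, n_samples = 20000, fold_range = c(0, 2),
                              seed = 1L) {
  stopifnot(n_samples >= 1, fold_range[1] >= 0,
            fold_range[2] >= fold_range[1])
  if (is.numeric(config)) {
    tab <- config
    if (is.null(names(tab))) names(tab) <- paste0("p", seq_along(tab))
    free <- names(tab)
  } else {
    tab <- config$conductance_table
    free <- free_parameters(config)
  }
  if (any(tab[free] == 0))
    stop("degenerate sampling range: baseline density is zero for ",
         paste(free[tab[free] == 0], collapse = ", "))
  m <- matrix(rep(tab, each = n_samples), nrow = n_samples,
              dimnames = list(NULL, names(tab)))
  withr::with_seed(seed, {
    for (k in free)
      m[, k] <- tab[k] * stats::runif(n_samples, fold_range[1], fold_range[2])
  })
  m
}

#' Classify a sampled population by validity
#'
#' @param samples matrix from [sample_population()] (or any matrix whose
#'   columns the evaluator understands).
#' @param evaluator function mapping one row (named vector) to the Pareto
#'   efficiency `P`.
#' @param threshold validity threshold on `P` (strict, default 2).
#' @return A `population_result`: the samples, per-row `P`, logical `valid`
#'   flags, `valid_fraction`, and its 95% Wilson `ci`.
#' @export
classify_population <- function(samples, evaluator, threshold = 2) {
  if (is.null(dim(samples)) || nrow(samples) == 0) stop("empty sample matrix")
  P <- vapply(seq_len(nrow(samples)), function(i) evaluator(samples[i, ]),
              numeric(1))
  valid <- P < threshold
  structure(list(samples = samples, P = P, valid = valid,
                 valid_fraction = mean(valid),
                 ci = wilson_ci(sum(valid), length(valid))),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("<population_result>: %d samples, valid fraction %.4f (95%% CI %.4f-%.4f)\n",
              length(x$P), x$valid_fraction, x$ci["lo"], x$ci["hi"]))
  invisible(x)
}

#' Valid fraction as a function of sampling range around a baseline
#'
#' For each half-width `w`, samples free densities uniformly in
#' `[1 - w, 1 + w] x baseline` (frozen keys fixed) and reports the valid
#' fraction with its confidence interval.
#'
#' @param config baseline [neuron_config()]; should itself be valid under
#'   the evaluator.
#' @param half_widths vector of half-widths in `(0, 1]` (0 allowed:
#'   degenerate range).
#' @param n_per samples per half-width (default 5000).
#' @param evaluator row evaluator as in [classify_population()].
#' @param seed RNG seed.
#' @return Data frame with `half_width`, `valid_fraction`, `ci_lo`, `ci_hi`.
#' @export
range_sweep <- function(config, half_widths, n_per = 5000, evaluator,
                        seed = 1L) {
  stopifnot(all(half_widths >= 0), all(half_widths <= 1))
  rows <- lapply(seq_along(half_widths), function(i) {
    w <- half_widths[i]
    s <- sample_population(config, n_per, fold_range = c(1 - w, 1 + w),
                           seed = seed + i)
    res <- classify_population(s, evaluator)
    data.frame(half_width = w, valid_fraction = res$valid_fraction,
               ci_lo = res$ci["lo"], ci_hi = res$ci["hi"], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlations among valid parameter vectors
#'
#' Pearson `r` for every parameter pair over the supplied rows, with
#' two-sided p-values from the exact t transform and significance flags at
#' `p < alpha` (no multiple-testing correction). Constant columns yield
#' missing correlations and are never flagged.
#'
#' @param valid_rows matrix of parameter vectors (rows = models).
#' @param alpha flagging threshold (default 0.01).
#' @return List with matrices `r`, `p`, `flag`.
#' @export
pairwise_correlations <- function(valid_rows, alpha = 0.01) {
  n <- nrow(valid_rows)
  if (is.null(n) || n < 3) stop("need at least 3 rows for correlations")
  keep_sd <- apply(valid_rows, 2, stats::sd)
  r <- suppressWarnings(stats::cor(valid_rows))
  r[keep_sd == 0, ] <- NA_real_
  r[, keep_sd == 0] <- NA_real_
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  diag(p) <- NA_real_
  flag <- !is.na(p) & p < alpha
  diag(flag) <- FALSE
  list(r = r, p = p, flag = flag)
}

#' Random walk in parameter space until validity is lost
#'
#' Per step, every free parameter is multiplied by an independent uniform
#' factor in `[1 - step_fraction, 1 + step_fraction]` (one step = changes in
#' all parameters). The walk halts at the first invalid state and returns
#' the number of completed valid steps.
#'
#' @param start named parameter vector, valid under the evaluator.
#' @param evaluator row evaluator returning `P`.
#' @param step_fraction relative step half-range (default 0.05).
#' @param max_steps cap on steps.
#' @param seed RNG seed.
#' @param threshold validity threshold (strict, default 2).
#' @return Integer: steps survived.
#' @export
random_walk <- function(start, evaluator, step_fraction = 0.05,
                        max_steps = 1000, seed = 1L, threshold = 2) {
  if (!(evaluator(start) < threshold)) stop("random walk must start from a valid point")
  withr::with_seed(seed, {
    x <- start
    n <- length(x)
    for (s in seq_len(max_steps)) {
      x <- x * stats::runif(n, 1 - step_fraction, 1 + step_fraction)
      if (!(evaluator(x) < threshold)) return(s - 1L)
    }
    max_steps
  })
}

#' Ensemble of random walks
#'
#' Repeats [random_walk()] `reps` times (cycling over the supplied start
#' vectors) and summarizes the survival distribution with a bin-width-4
#' histogram and the mean number of surviving steps.
#'
#' @param starts a single named vector or a list of valid start vectors.
#' @param evaluator,step_fraction,max_steps,threshold as [random_walk()].
#' @param reps number of walks (default 2000).
#' @param seed RNG seed (each walk gets a derived child seed).
#' @param bin_width histogram bin width in steps (default 4).
#' @return A `walk_result`: `steps` per repetition, `histogram` data frame
#'   (`bin_lo`, `bin_hi`, `count`), and `mean_steps`.
#' @export
walk_ensemble <- function(starts, evaluator, reps = 2000, step_fraction = 0.05,
                          max_steps = 1000, seed = 1L, threshold = 2,
                          bin_width = 4) {
  if (!is.list(starts)) starts <- list(starts)
  steps <- vapply(seq_len(reps), function(i) {
    child <- as.integer((as.numeric(seed) * 48271 + i) %% 2147483647)
    random_walk(starts[[(i - 1L) %% length(starts) + 1L]], evaluator,
                step_fraction, max_steps, seed = child,
                threshold = threshold)
  }, numeric(1))
  edges <- seq(0, (max(steps) %/% bin_width + 1) * bin_width, by = bin_width)
  counts <- as.vector(table(cut(steps, edges, right = FALSE,
                                include.lowest = FALSE)))
  structure(list(steps = steps,
                 histogram = data.frame(bin_lo = utils::head(edges, -1),
                                        bin_hi = edges[-1], count = counts),
                 mean_steps = mean(steps)),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("<walk_result>: %d walks, mean %.1f steps (max %d)\n",
              length(x$steps), x$mean_steps, max(x$steps)))
  invisible(x)
}

#' Expand the 5-channel model with artificial channel isoforms
#'
#' Adds `k` isoforms of the remaining potassium (BK) and calcium (Cav22)
#' channels (alternating BK, Cav22, BK, ...) via [make_isoform()]. The
#' family's default densities split each parent channel's baseline density
#' evenly over the parent and its isoforms. Candidate conductance sets are
#' then sampled uniformly in `[0, 2] x` those defaults; the three
#' best-fitness candidates are refined with [conjugate_direction_search()]
#' against the 5-channel baseline's targets and the best refined model is
#' returned.
#'
#' @param base5 the 5-channel baseline [neuron_config()].
#' @param k number of isoforms to add (>= 0).
#' @param initial_sample_size random candidates before refinement (>= 3
#'   unless `k = 0`).
#' @param search a [search_config()].
#' @param solver a [solver_options()].
#' @param seed RNG seed.
#' @param sd_fractions target SD fractions for the baseline targets.
#' @return List: `config` (expanded model with the best parameters applied),
#'   `P` (its Pareto efficiency), `valid` flag, `n_candidates`, `k`.
#' @export
expand_isoforms <- function(base5, k, initial_sample_size = 1000,
                            search = search_config(), solver = solver_options(),
                            seed = 1L, sd_fractions = 0.2) {
  stopifnot(k >= 0)
  targets <- generate_feature_targets(base5, sd_fractions = sd_fractions,
                                      solver = solver)
  cfg <- base5
  if (k > 0) {
    parents <- rep(c("BK", "Cav22"), length.out = k)
    ch_by_name <- stats::setNames(cfg$channels,
                                  vapply(cfg$channels, `[[`, character(1), "name"))
    isoforms <- lapply(seq_len(k), function(i) {
      make_isoform(ch_by_name[[parents[i]]], rng_seed = seed * 1000L + i,
                   name = sprintf("%s_iso%d", parents[i], i))
    })
    channels <- c(cfg$channels, isoforms)
    # split each parent's density over parent + isoforms, per region
    tab <- cfg$conductance_table
    for (parent in unique(parents)) {
      copies <- 1L + sum(parents == parent)
      pkeys <- grep(paste0("^", parent, "@"), names(tab), value = TRUE)
      tab[pkeys] <- tab[pkeys] / copies
      for (iso in isoforms[parents == parent]) {
        ikeys <- paste0(iso$name, "@", iso$regions)
        tab[ikeys] <- tab[sub(paste0("^", iso$name), parent, ikeys)]
      }
    }
    cfg <- neuron_config(cfg$compartments, channels, cfg$ca_pool, tab,
                         frozen_parameters = cfg$frozen_parameters)
  }
  objective <- pareto_objective(cfg, targets = targets, solver = solver)
  base <- parameter_vector(cfg)
  if (k == 0) {
    P <- objective(base)
    return(list(config = cfg, P = P, valid = P < 2, n_candidates = 0L, k = k))
  }
  stopifnot(initial_sample_size >= 3)
  cand <- withr::with_seed(seed, {
    lapply(seq_len(initial_sample_size), function(i)
      base * stats::runif(length(base), 0, 2))
  })
  Ps <- vapply(cand, objective, numeric(1))
  top3 <- order(Ps)[1:3]
  refined <- lapply(seq_along(top3), function(j) {
    sc <- search
    sc$rng_seed <- seed * 10L + j
    start <- pmax(cand[[top3[j]]], 1e-6 * base)  # search needs positivity
    conjugate_direction_search(objective, start, sc)
  })
  bestj <- which.min(vapply(refined, `[[`, numeric(1), "best_P"))
  best <- refined[[bestj]]
  list(config = apply_parameters(cfg, best$best), P = best$best_P,
       valid = best$best_P < 2, n_candidates = length(cand), k = k,
       refined = refined)
}

#' Pairwise hyperplane interpolation between two valid models
#'
#' Evaluates the nine convex combinations `w A + (1 - w) B` for
#' `w = 0.1, ..., 0.9`; the pair is connected iff every interpolant is valid.
#'
#' @param vectorA,vectorB named parameter vectors with identical layout.
#' @param evaluator row evaluator returning `P`.
#' @param threshold validity threshold (strict).
#' @return A `hyperplane_result` with `weights`, `P`, and `connected`.
#' @export
hyperplane_pair <- function(vectorA, vectorB, evaluator, threshold = 2) {
  if (length(vectorA) != length(vectorB) ||
      !identical(names(vectorA), names(vectorB)))
    stop("parameter layouts of the two vectors differ")
  w <- seq(0.1, 0.9, by = 0.1)
  P <- vapply(w, function(wi) evaluator(wi * vectorA + (1 - wi) * vectorB),
              numeric(1))
  structure(list(weights = w, P = P, connected = all(P < threshold)),
            class = "hyperplane_result")
}

#' Triplet hyperplane grid through three valid models
#'
#' Weights `(w1, w2)` range over `{-1.5, -1.46, ..., 2.5}` (step 0.04) with
#' `w3 = 1 - w1 - w2`. Grid points whose combined parameter vector has any
#' negative entry are masked out and carry no fitness; the rest are
#' evaluated (the evaluator's non-spiking sentinel, 6, applies as usual).
#'
#' @param vectorA,vectorB,vectorC named parameter vectors, identical layout.
#' @param evaluator row evaluator returning `P`.
#' @param step grid step (default 0.04).
#' @param range weight range (default `c(-1.5, 2.5)`).
#' @param include_vertices also evaluate the three unit-weight vertices
#'   (which the regular 0.04 grid does not contain), flagged in the `vertex`
#'   column.
#' @return A `hyperplane_result` with a data frame `grid` (`w1`, `w2`,
#'   `masked`, `vertex`, `P`).
#' @export
hyperplane_triplet <- function(vectorA, vectorB, vectorC, evaluator,
                               step = 0.04, range = c(-1.5, 2.5),
                               include_vertices = TRUE) {
  vs <- list(vectorA, vectorB, vectorC)
  for (v in vs[-1])
    if (length(v) != length(vs[[1]]) || !identical(names(v), names(vs[[1]])))
      stop("parameter layouts of the three vectors differ")
  w <- seq(range[1], range[2], by = step)
  grid <- expand.grid(w1 = w, w2 = w)
  grid$vertex <- FALSE
  if (include_vertices) {
    vert <- data.frame(w1 = c(1, 0, 0), w2 = c(0, 1, 0), vertex = TRUE)
    vert <- vert[!(paste(vert$w1, vert$w2) %in% paste(grid$w1, grid$w2)), ]
    grid <- rbind(grid, vert)
  }
  res <- vapply(seq_len(nrow(grid)), function(i) {
    w1 <- grid$w1[i]; w2 <- grid$w2[i]; w3 <- 1 - w1 - w2
    x <- w1 * vectorA + w2 * vectorB + w3 * vectorC
    if (any(x < 0)) c(1, NA_real_) else c(0, evaluator(x))
  }, numeric(2))
  grid$masked <- res[1, ] == 1
  grid$P <- res[2, ]
  structure(list(grid = grid), class = "hyperplane_result")
}
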