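#' Configuration of the conjugate-direction search
#'
#' Successive line minimizations in conjugate directions with two escape
#' mechanisms for flat regions of the cost landscape: step-size escalation
#' (probe step grows in 5-percentage-point increments up to 50%) and
#' randomized restarts (each coordinate multiplied by an independent uniform
#' factor, with range growing from +/-10% in +/-10% increments up to +/-50%).
#'
#' @param probe_step initial relative probe/line step (fraction, default 0.05).
#' @param max_probe_step escalation ceiling (default 0.50).
#' @param escalation_step escalation increment (default 0.05).
#' @param randomization_start,randomization_step,randomization_max the
#'   randomized-restart schedule (defaults 0.10, 0.10, 0.50).
#' @param success_threshold terminate when `P` falls below this (default 2).
#' @param max_outer_iterations cap on outer sweeps (default 50).
#' @param max_line_evals objective-evaluation cap per line minimization.
#' @param stall_tol minimum improvement counted as progress (default 1e-6).
#' @param rng_seed seed for the randomized restarts.
#' @return An object of class `search_config`.
#' @export
search_config <- function(probe_step = 0.05, max_probe_step = 0.50,
                          escalation_step = 0.05,
                          randomization_start = 0.10,
                          randomization_step = 0.10,
                          randomization_max = 0.50,
                          success_threshold = 2,
                          max_outer_iterations = 50,
                          max_line_evals = 20,
                          stall_tol = 1e-6,
                          rng_seed = 1L) {
  stopifnot(probe_step > 0, probe_step <= max_probe_step, max_probe_step <= 1,
            success_threshold > 0, max_outer_iterations >= 1,
            max_line_evals >= 3)
  structure(as.list(environment()), class = "search_config")
}

#' Central-difference slope of an objective along one coordinate
#'
#' Evaluates the objective at `(1 - s) x_d` and `(1 + s) x_d` and returns the
#' central-difference slope. A dimension is flagged flat when the two probe
#' values are identical.
#'
#' @param objective function mapping a named parameter vector to a scalar.
#' @param point named, strictly positive parameter vector.
#' @param dimension name or index of the probed coordinate.
#' @param step_fraction relative probe step `s`.
#' @return List with `slope`, `flat`, and the two probe values.
#' @export
probe_direction <- function(objective, point, dimension, step_fraction = 0.05) {
  stopifnot(all(point > 0), step_fraction > 0, step_fraction < 1)
  if (is.character(dimension)) dimension <- match(dimension, names(point))
  xp <- point; xp[dimension] <- point[dimension] * (1 + step_fraction)
  xm <- point; xm[dimension] <- point[dimension] * (1 - step_fraction)
  fp <- objective(xp); fm <- objective(xm)
  if (!is.finite(fp) || !is.finite(fm))
    stop("objective returned a non-finite value during probing")
  list(slope = unname((fp - fm) / (2 * step_fraction * point[dimension])),
       flat = fp == fm, f_plus = fp, f_minus = fm)
}

# Multiplicative-scale line minimization: candidates are
# pmax(0, point + t * u) where u is the direction scaled so that t = 1
# changes the largest relative coordinate by `step`. Expands the bracket by
# the golden ratio while descending, then refines by golden-section; never
# returns a worse point than the input.
line_minimize_impl <- function(objective, point, direction, f0, step,
                               max_evals = 20) {
  stopifnot(any(direction != 0))
  rel <- abs(direction) / pmax(point, .Machine$double.eps)
  u <- direction * (step / max(rel))
  cand <- function(t) pmax(point + t * u, 0)
  evals <- 0L
  fval <- function(t) {
    evals <<- evals + 1L
    v <- objective(cand(t))
    if (!is.finite(v)) Inf else v
  }
  gr <- (1 + sqrt(5)) / 2
  fp <- fval(1); fm <- fval(-1)
  if (is.infinite(fp) && is.infinite(fm)) stop("all line candidates non-finite")
  # pick descending side; if neither improves, return input
  if (min(fp, fm) >= f0) {
    return(list(point = point, value = f0, evals = evals))
  }
  sgn <- if (fp <= fm) 1 else -1
  f_prev <- f0; t_prev <- 0
  f_cur <- min(fp, fm); t_cur <- sgn
  # expand until the function turns upward or the budget is spent
  while (evals < max_evals - 2L) {
    t_next <- t_cur * gr
    f_next <- fval(sgn * abs(t_next))
    if (!is.finite(f_next) || f_next >= f_cur) {
      t_hi <- t_next
      break
    }
    t_prev <- t_cur; f_prev <- f_cur
    t_cur <- t_next; f_cur <- f_next
    t_hi <- t_cur * gr
  }
  if (!exists("t_hi", inherits = FALSE)) t_hi <- t_cur * gr
  # golden-section refinement on [t_prev, t_hi] (signed)
  a <- abs(t_prev); b <- abs(t_hi)
  x1 <- b - (b - a) / gr; x2 <- a + (b - a) / gr
  f1 <- fval(sgn * x1); f2 <- fval(sgn * x2)
  while (evals < max_evals) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - (b - a) / gr
      f1 <- fval(sgn * x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + (b - a) / gr
      f2 <- fval(sgn * x2)
    }
  }
  ts <- c(0, sgn * abs(t_cur), sgn * x1, sgn * x2)
  fs <- c(f0, f_cur, f1, f2)
  k <- which.min(fs)
  list(point = cand(ts[k]), value = fs[k], evals = evals)
}

#' Line minimization along a direction
#'
#' @param objective scalar objective over named parameter vectors.
#' @param point named non-negative starting vector.
#' @param direction search direction (same length); need not be normalized.
#' @param config a [search_config()]; `probe_step` sets the initial bracket
#'   and `max_line_evals` the evaluation cap.
#' @return The best point found (never worse than the input).
#' @export
line_minimize <- function(objective, point, direction, config = search_config()) {
  f0 <- objective(point)
  line_minimize_impl(objective, point, direction, f0,
                     step = config$probe_step,
                     max_evals = config$max_line_evals)$point
}

#' Derivative-free conjugate-direction search for valid parameter vectors
#'
#' Powell-style outer sweeps of line minimizations along a maintained
#' direction set, with periodic replacement of the direction of largest
#' decrease by the sweep's aggregate displacement. When a sweep stalls
#' (improvement below `stall_tol`), the step size escalates in
#' 5-percentage-point increments up to 50%; if the landscape stays flat the
#' current point is randomized coordinate-wise over an iteratively widening
#' range (+/-10% up to +/-50%) and the direction set is reset to the
#' coordinate axes. Terminates when the objective falls below
#' `success_threshold`, when escalation and randomization have been
#' exhausted twice without progress (`stalled`), or at the iteration cap.
#'
#' @param objective scalar objective (e.g. a [pareto_objective()]).
#' @param start named, strictly positive starting vector.
#' @param config a [search_config()].
#' @return A `search_result`: `best` vector, `best_P`, `trajectory` of the
#'   best objective value per outer iteration, `iterations`, `termination`
#'   (one of `threshold_met`, `stalled`, `max_iterations`) and an `events`
#'   data frame (iteration, action, P, n_evals).
#' @export
conjugate_direction_search <- function(objective, start, config = search_config()) {
  stopifnot(all(start > 0), !is.null(names(start)))
  withr::with_seed(config$rng_seed, {
    n <- length(start)
    dirs <- diag(n)
    x <- start
    fx <- objective(x)
    best <- x; f_best <- fx
    events <- list(list(iteration = 0L, action = "probe", P = fx, n_evals = 1L))
    trajectory <- numeric(0)
    step <- config$probe_step
    rand_r <- NA_real_       # current randomization range (NA: not randomizing)
    cycles_exhausted <- 0L   # full escalation+randomization cycles without progress
    termination <- "max_iterations"
    iter <- 0L
    while (iter < config$max_outer_iterations) {
      if (f_best < config$success_threshold) {
        termination <- "threshold_met"
        break
      }
      iter <- iter + 1L
      x0 <- x; f0 <- fx
      decrease <- numeric(n)
      for (i in seq_len(n)) {
        r <- line_minimize_impl(objective, x, dirs[, i], fx, step,
                                config$max_line_evals)
        decrease[i] <- fx - r$value
        x <- r$point; fx <- r$value
        events[[length(events) + 1L]] <-
          list(iteration = iter, action = "line", P = fx, n_evals = r$evals)
      }
      d <- x - x0
      if (any(d != 0)) {
        r <- line_minimize_impl(objective, x, d, fx, step, config$max_line_evals)
        x <- r$point; fx <- r$value
        events[[length(events) + 1L]] <-
          list(iteration = iter, action = "line", P = fx, n_evals = r$evals)
        dirs[, which.max(decrease)] <- d / sqrt(sum(d^2))
      }
      if (fx < f_best) { best <- x; f_best <- fx }
      trajectory <- c(trajectory, f_best)
      improved <- (f0 - fx) > config$stall_tol
      if (improved) {
        step <- config$probe_step
        rand_r <- NA_real_
        next
      }
      # plateau handling: escalate first, then randomize
      if (step < config$max_probe_step - 1e-12) {
        step <- min(step + config$escalation_step, config$max_probe_step)
        events[[length(events) + 1L]] <-
          list(iteration = iter, action = "escalate", P = f_best, n_evals = 0L)
      } else {
        rand_r <- if (is.na(rand_r)) config$randomization_start
                  else rand_r + config$randomization_step
        if (rand_r > config$randomization_max + 1e-12) {
          cycles_exhausted <- cycles_exhausted + 1L
          if (cycles_exhausted >= 2L) {
            termination <- "stalled"
            break
          }
          step <- config$probe_step
          rand_r <- NA_real_
          next
        }
        x <- best * stats::runif(n, 1 - rand_r, 1 + rand_r)
        fx <- objective(x)
        events[[length(events) + 1L]] <-
          list(iteration = iter, action = "randomize", P = fx, n_evals = 1L)
        if (fx < f_best) { best <- x; f_best <- fx }
        if (rand_r >= config$randomization_max - 1e-12) {
          # full randomization sweep done: fresh conjugate construction
          dirs <- diag(n)
        }
      }
    }
    if (f_best < config$success_threshold) termination <- "threshold_met"
    structure(list(best = best, best_P = f_best, trajectory = trajectory,
                   iterations = iter, termination = termination,
                   events = do.call(rbind, lapply(events, as.data.frame))),
              class = "search_result")
  })
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>: best P = ", signif(x$best_P, 4), " after ",
      x$iterations, " outer iterations (", x$termination, ")\n", sep = "")
  invisible(x)
}

#' Knock out a channel and refit the remaining conductances
#'
#' Sets every density of the named channel to zero, freezes those entries,
#' and reoptimizes the remaining free parameters against the targets of the
#' intact baseline. Knocking out the passive backbone (`pas`, `Kir21`) is an
#' error.
#'
#' @param config the intact baseline [neuron_config()].
#' @param channel_name channel to block.
#' @param targets [feature_targets()] of the intact baseline; generated from
#'   `config` when `NULL`.
#' @param search a [search_config()].
#' @param solver a [solver_options()].
#' @param sd_fractions target SD fractions when `targets` is `NULL`.
#' @return A `search_result` whose `best` vector spans the reduced dimension
#'   set, plus elements `config` (the knocked-out model with the best vector
#'   applied) and `knocked_out`.
#' @export
knockout_refit <- function(config, channel_name, targets = NULL,
                           search = search_config(), solver = solver_options(),
                           sd_fractions = 0.2) {
  ch_names <- vapply(config$channels, `[[`, character(1), "name")
  if (!(channel_name %in% ch_names))
    stop("channel not present in the model: ", channel_name)
  if (channel_name %in% c("pas", "Kir21"))
    stop("cannot knock out the frozen passive backbone channel ", channel_name)
  if (is.null(targets))
    targets <- generate_feature_targets(config, sd_fractions = sd_fractions,
                                        solver = solver)
  ko_keys <- grep(paste0("^", channel_name, "@"), names(config$conductance_table),
                  value = TRUE)
  ko <- config
  ko$conductance_table[ko_keys] <- 0
  ko$frozen_parameters <- union(ko$frozen_parameters, ko_keys)
  objective <- pareto_objective(ko, targets = targets, solver = solver)
  start <- parameter_vector(ko)
  res <- conjugate_direction_search(objective, start, search)
  res$config <- apply_parameters(ko, res$best)
  res$knocked_out <- channel_name
  res
}
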