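# Shared fixtures for the test suite. Baseline models and their sessions are
# built once per test run; experiment-scale checks use the coarse population
# solver (dt = 0.1 ms, 300 ms settle), unit-level numerics the fine one.

baselines <- make_baseline_models()

fine_solver <- solver_options(dt = 0.025)
pop_solver <- solver_options(dt = 0.1, settle_ms = 300)

# single-compartment passive cell: analytic RC reference
passive_config <- function(g_leak = 0.05, area = 1e-4, cm = 1) {
  neuron_config(
    list(compartment_spec("soma", area = area, capacitance = cm)),
    list(channel_spec("pas", ion = "leak", reversal = -80, regions = "all")),
    calcium_pool_spec(),
    conductance_table = c("pas@all" = g_leak))
}

# toy-rule row evaluator: P = 6 unless the row mean is within tol of 1
toy_rule_evaluator <- function(tol = 0.015) {
  function(row) if (abs(mean(row) - 1) < tol) 0 else 6
}

# objective wrapper that counts evaluations
counting <- function(f) {
  n <- 0L
  g <- function(x) {
    n <<- n + 1L
    f(x)
  }
  attr(g, "count") <- function() n
  g
}
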