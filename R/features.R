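#' @keywords internal
feature_names <- function() {
  c("spike_count", "latency", "threshold", "mean_amplitude",
    "fahp_amplitude", "abs_fahp_amplitude", "ap_width", "isi_first",
    "adaptation_index")
}

#' Default per-feature standard-deviation floors
#'
#' Floors keep self-generated target SDs away from zero: 0.5 for the spike
#' count, 1 ms for timing features, 1 mV for voltage features and 0.05 for
#' the unitless adaptation index.
#'
#' @return Named numeric vector over the nine features.
#' @export
default_sd_floors <- function() {
  c(spike_count = 0.5, latency = 1, threshold = 1, mean_amplitude = 1,
    fahp_amplitude = 1, abs_fahp_amplitude = 1, ap_width = 1,
    isi_first = 1, adaptation_index = 0.05)
}

#' Detect action potentials in a voltage trace
#'
#' A spike onset is an upward crossing of the somatic dV/dt through
#' `rate_threshold`; the voltage at onset defines the spike threshold. The
#' peak is the first local maximum after onset, and the fast
#' after-hyperpolarisation (fAHP) is the minimum potential within 5 ms after
#' the peak. After an onset, no new onset is accepted until the potential has
#' fallen back below that spike's threshold (refractory rule, prevents double
#' counting on noisy rises).
#'
#' @param trace a `voltage_trace` (somatic Vm is used).
#' @param rate_threshold dV/dt criterion (mV/ms), default 15.
#' @return A data frame with one row per spike: `onset_time`, `peak_time`,
#'   `peak_vm`, `threshold_vm`, `fahp_vm` (times in ms on the trace's time
#'   base) plus the sample indices `onset_index` and `peak_index`.
#' @export
detect_spikes <- function(trace, rate_threshold = 15) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$dt > 1)
    stop("dt = ", trace$dt, " ms is too coarse for the dV/dt spike criterion")
  vm <- soma_vm(trace)
  n <- length(vm)
  if (n < 2) stop("trace too short for spike detection")
  rate <- diff(vm) / trace$dt
  cand <- which(rate > rate_threshold)
  empty <- data.frame(onset_time = numeric(0), peak_time = numeric(0),
                      peak_vm = numeric(0), threshold_vm = numeric(0),
                      fahp_vm = numeric(0), onset_index = integer(0),
                      peak_index = integer(0))
  if (!length(cand)) return(empty)
  w5 <- max(1L, round(5 / trace$dt))
  onset_i <- peak_i <- integer(0)
  thr_v <- fahp_v <- numeric(0)
  rearm <- 0L
  for (i in cand) {
    if (i <= rearm) next
    thr_vm <- vm[i]
    # first local maximum after onset
    j <- i
    while (j < n && vm[j + 1] >= vm[j]) j <- j + 1L
    peak <- j
    fwin <- vm[seq(min(peak + 1L, n), min(peak + w5, n))]
    onset_i <- c(onset_i, i); peak_i <- c(peak_i, peak)
    thr_v <- c(thr_v, thr_vm)
    fahp_v <- c(fahp_v, if (length(fwin)) min(fwin) else NA_real_)
    # refractory: wait until Vm falls below this spike's threshold
    k <- peak
    while (k < n && vm[k] >= thr_vm) k <- k + 1L
    rearm <- k
  }
  if (!length(onset_i)) return(empty)
  data.frame(onset_time = trace$time[onset_i], peak_time = trace$time[peak_i],
             peak_vm = vm[peak_i], threshold_vm = thr_v, fahp_vm = fahp_v,
             onset_index = onset_i, peak_index = peak_i)
}

#' Spike-frequency adaptation index
#'
#' `AI = 1 - ISI_1 / ISI_end`; defined only when at least two interspike
#' intervals exist.
#'
#' @param isis vector of interspike intervals (ms, > 0).
#' @return The adaptation index, or `NA` when fewer than two ISIs exist.
#' @export
adaptation_index <- function(isis) {
  if (length(isis) && any(isis <= 0)) stop("non-positive interspike interval")
  if (length(isis) < 2) return(NA_real_)
  1 - isis[1] / isis[length(isis)]
}

# AP width at half amplitude for one spike, with linear interpolation between
# samples. Half height is threshold + (peak - threshold)/2.
ap_half_width <- function(time, vm, onset_idx, peak_idx, thr_vm, n) {
  half <- thr_vm + (vm[peak_idx] - thr_vm) / 2
  iu <- peak_idx
  while (iu > onset_idx && vm[iu - 1] > half) iu <- iu - 1L
  if (iu == 1L || vm[iu - 1] > half) return(NA_real_)
  t_up <- time[iu - 1] + (half - vm[iu - 1]) / (vm[iu] - vm[iu - 1]) *
    (time[iu] - time[iu - 1])
  id <- peak_idx
  while (id < n && vm[id + 1] > half) id <- id + 1L
  if (id == n) return(NA_real_)
  t_dn <- time[id] + (half - vm[id]) / (vm[id + 1] - vm[id]) *
    (time[id + 1] - time[id])
  t_dn - t_up
}

# All nine features from one trace; latency and the spike-count window are
# measured from stimulus onset.
trace_features <- function(trace, rate_threshold = 15) {
  p <- trace$protocol
  ev <- detect_spikes(trace, rate_threshold)
  t_on <- trace$time[trace$onset_index]
  in_win <- ev$onset_time >= t_on & ev$onset_time < t_on + p$step_ms
  ev <- ev[in_win, , drop = FALSE]
  k <- nrow(ev)
  f <- stats::setNames(rep(NA_real_, 9), feature_names())
  f["spike_count"] <- k
  if (k >= 1) {
    f["latency"] <- ev$onset_time[1] - t_on
    f["threshold"] <- mean(ev$threshold_vm)
    f["mean_amplitude"] <- mean(ev$peak_vm - ev$threshold_vm)
    # signed fAHP: threshold minus post-spike minimum (positive when the
    # trough undershoots the threshold)
    f["fahp_amplitude"] <- mean(ev$threshold_vm - ev$fahp_vm)
    f["abs_fahp_amplitude"] <- abs(f["fahp_amplitude"])
    vm <- soma_vm(trace)
    n <- length(vm)
    widths <- vapply(seq_len(k), function(i) {
      ap_half_width(trace$time, vm, ev$onset_index[i], ev$peak_index[i],
                    ev$threshold_vm[i], n)
    }, numeric(1))
    f["ap_width"] <- mean(widths, na.rm = TRUE)
    if (all(is.na(widths))) f["ap_width"] <- NA_real_
  }
  if (k >= 2) f["isi_first"] <- ev$onset_time[2] - ev$onset_time[1]
  if (k >= 3) f["adaptation_index"] <- adaptation_index(diff(ev$onset_time))
  f
}

#' Extract the nine spike features from the standard protocol pair
#'
#' Both traces must come from the standard protocol (50 ms prerun, 200 ms
#' step, 50 ms tail) at 50 and 90 pA. Features whose prerequisites are absent
#' (e.g. no spikes, or fewer than two ISIs) carry `NA`.
#'
#' @param trace_50,trace_90 `voltage_trace` objects at 50 and 90 pA.
#' @param rate_threshold spike-detection dV/dt criterion (mV/ms).
#' @return A `feature_vector`: list with named numeric vectors `pA50` and
#'   `pA90` over the nine features.
#' @export
extract_features <- function(trace_50, trace_90, rate_threshold = 15) {
  for (tr in list(trace_50, trace_90)) {
    p <- tr$protocol
    if (is.null(p) || p$pre_ms != 50 || p$step_ms != 200 || p$post_ms != 50)
      stop("protocol mismatch: expected 50/200/50 ms segments")
  }
  structure(list(pA50 = trace_features(trace_50, rate_threshold),
                 pA90 = trace_features(trace_90, rate_threshold)),
            class = "feature_vector")
}

#' Feature targets (experimental-style means and SDs)
#'
#' @param means,sds lists with named numeric vectors `pA50` and `pA90` over
#'   the nine features (units as the features; `NA` where undefined).
#' @param sd_floors named per-feature floors; SDs are raised to the floor.
#' @return An object of class `feature_targets`.
#' @export
feature_targets <- function(means, sds, sd_floors = default_sd_floors()) {
  fl <- default_sd_floors()
  fl[names(sd_floors)] <- sd_floors
  for (pr in c("pA50", "pA90")) {
    stopifnot(setequal(names(means[[pr]]), feature_names()),
              setequal(names(sds[[pr]]), feature_names()))
    means[[pr]] <- means[[pr]][feature_names()]
    sds[[pr]] <- pmax(sds[[pr]][feature_names()], fl)
    if (any(!is.na(sds[[pr]]) & sds[[pr]] <= 0))
      stop("feature SD not positive after applying floors")
  }
  structure(list(means = means, sds = sds, sd_floors = fl),
            class = "feature_targets")
}

#' Multi-objective fitness and validity of a feature vector
#'
#' Per defined feature and protocol, the fitness is the absolute deviation
#' from the target mean in units of the target SD,
#' \eqn{F_i = |SF_i - \bar{SF}_{i}| / SD_{i}}. The Pareto efficiency `P` is
#' the maximum over all defined (feature, protocol) pairs, and a model is
#' valid iff `P < 2` (strict). A model with no spikes at either amplitude
#' cannot define the spike-shape features; its `P` is set to the sentinel 6.
#' Features undefined in the candidate or in the targets are skipped.
#'
#' @param features a [extract_features()] result.
#' @param targets a [feature_targets()] object.
#' @param sentinel `P` assigned to non-spiking models (default 6).
#' @return A `fitness_result`: list with per-feature fitness matrices `F`
#'   (features x protocols), `P`, `valid`, `sentinel_applied`.
#' @export
feature_fitness <- function(features, targets, sentinel = 6) {
  stopifnot(inherits(features, "feature_vector"),
            inherits(targets, "feature_targets"))
  Fm <- matrix(NA_real_, 9, 2, dimnames = list(feature_names(), c("pA50", "pA90")))
  for (pr in c("pA50", "pA90")) {
    sf <- features[[pr]][feature_names()]
    mu <- targets$means[[pr]]
    sd <- targets$sds[[pr]]
    ok <- !is.na(sf) & !is.na(mu) & !is.na(sd)
    Fm[ok, pr] <- abs(sf[ok] - mu[ok]) / sd[ok]
  }
  non_spiking <- features$pA50[["spike_count"]] == 0 &&
    features$pA90[["spike_count"]] == 0
  if (non_spiking) {
    P <- sentinel
  } else {
    P <- max(Fm, na.rm = TRUE)
  }
  structure(list(F = Fm, P = P, valid = P < 2,
                 sentinel_applied = non_spiking),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("<fitness_result>: P = ", signif(x$P, 4),
      if (x$valid) " (valid)" else " (invalid)",
      if (x$sentinel_applied) " [non-spiking sentinel]", "\n", sep = "")
  invisible(x)
}

#' Generate feature targets from a reference model
#'
#' Simulates the reference at 50 and 90 pA, takes its features as the target
#' means, and sets each SD to `max(sd_fraction * |mean|, floor)`. This
#' emulates experimental across-cell statistics when none are available; the
#' reference model evaluates to `P = 0` against its own targets.
#'
#' @param reference a [neuron_config()] that spikes at 90 pA.
#' @param sd_fractions scalar or named per-feature vector (default 0.2).
#' @param sd_floors named per-feature floors (default [default_sd_floors()]).
#' @param solver the [solver_options()] used for the reference simulation;
#'   evaluate candidates with the same solver.
#' @return A [feature_targets()] object.
#' @export
generate_feature_targets <- function(reference, sd_fractions = 0.2,
                                     sd_floors = default_sd_floors(),
                                     solver = solver_options()) {
  session <- model_session(reference, solver)
  tr <- session_simulate(session, c(50, 90), record_full = FALSE)
  feats <- extract_features(tr[[1]], tr[[2]])
  if (feats$pA90[["spike_count"]] == 0)
    stop("reference model does not spike at 90 pA; cannot define targets")
  frac <- stats::setNames(rep(NA_real_, 9), feature_names())
  frac[] <- if (length(sd_fractions) == 1) sd_fractions else NA
  if (length(sd_fractions) > 1) frac[names(sd_fractions)] <- sd_fractions
  sds <- lapply(feats, function(sf) abs(sf) * frac)
  feature_targets(means = list(pA50 = feats$pA50, pA90 = feats$pA90),
                  sds = list(pA50 = sds$pA50, pA90 = sds$pA90),
                  sd_floors = sd_floors)
}

#' Build a Pareto-efficiency objective for a model family
#'
#' Returns a function mapping a free-parameter vector (named, over
#' [free_parameters()] of `config`) to the Pareto efficiency `P`. The
#' returned objective carries an evaluation counter (see
#' [evaluation_count()]) and reuses one compiled simulation session.
#'
#' @param config a [neuron_config()]; its current table supplies frozen
#'   entries and any parameters a vector omits.
#' @param targets a [feature_targets()] object; if `NULL`, targets are
#'   generated from `config` itself via [generate_feature_targets()].
#' @param solver a [solver_options()].
#' @param sd_fractions passed to [generate_feature_targets()] when targets
#'   are generated.
#' @return A function `f(par) -> P` with attributes for counting.
#' @export
pareto_objective <- function(config, targets = NULL, solver = solver_options(),
                             sd_fractions = 0.2) {
  if (is.null(targets))
    targets <- generate_feature_targets(config, sd_fractions = sd_fractions,
                                        solver = solver)
  session <- model_session(config, solver)
  table <- config$conductance_table
  free <- free_parameters(config)
  count <- 0L
  f <- function(par) {
    stopifnot(!is.null(names(par)),
              all(names(par) %in% names(table)))
    tab <- table
    tab[names(par)] <- par
    tr <- session_simulate(session, c(50, 90), table = tab, record_full = FALSE)
    feats <- extract_features(tr[[1]], tr[[2]])
    res <- feature_fitness(feats, targets)
    count <<- count + 1L
    if (!is.finite(res$P)) stop("non-finite Pareto efficiency")
    res$P
  }
  attr(f, "targets") <- targets
  attr(f, "free") <- free
  class(f) <- c("pareto_objective", "function")
  f
}

#' Number of objective evaluations performed so far
#' @param objective a [pareto_objective()] (or any closure with a `count`).
#' @return Integer count.
#' @export
evaluation_count <- function(objective) environment(objective)$count

#' Reset an objective's evaluation counter
#' @inheritParams evaluation_count
#' @return The objective, invisibly.
#' @export
reset_evaluation_count <- function(objective) {
  assign("count", 0L, envir = environment(objective))
  invisible(objective)
}
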