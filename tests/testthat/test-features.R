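test_that("spike detection finds constructed spikes and ignores slow ramps", {
  # flat trace: nothing to detect
  flat <- synth_trace(numeric(0))
  expect_identical(nrow(detect_spikes(flat)), 0L)
  # four embedded spikes at known onsets
  tr <- synth_trace(c(12, 50, 100, 180))
  ev <- detect_spikes(tr)
  expect_identical(nrow(ev), 4L)
  expect_equal(ev$onset_time, 50 + c(12, 50, 100, 180), tolerance = tr$dt * 1.5)
  # ramp with maximum slope 10 mV/ms stays below the 15 mV/ms criterion
  n <- 1201
  ramp <- synth_trace(numeric(0))
  ramp$vm[, 1] <- -80 + 10 * pmin(ramp$time, 30)  # 10 mV/ms for 30 ms
  expect_identical(nrow(detect_spikes(ramp)), 0L)
  # the same ramp above the criterion is one event
  ramp$vm[, 1] <- -80 + 20 * pmin(ramp$time, 5)
  expect_identical(nrow(detect_spikes(ramp)), 1L)
  # too-coarse sampling is rejected
  coarse <- synth_trace(numeric(0), dt = 0.025)
  coarse$dt <- 1.5
  expect_error(detect_spikes(coarse), "too coarse")
})

test_that("adaptation index follows 1 - ISI1/ISIend", {
  expect_equal(adaptation_index(c(10, 10, 10)), 0)
  expect_equal(adaptation_index(c(8, 12, 16)), 0.5)
  expect_true(is.na(adaptation_index(12)))
  expect_true(is.na(adaptation_index(numeric(0))))
  expect_error(adaptation_index(c(10, -1)), "non-positive")
})

test_that("feature extraction recovers constructed ground truth", {
  tr50 <- synth_trace(numeric(0), amplitude_pA = 50)
  tr90 <- synth_trace(c(12, 50, 100, 180), amplitude_pA = 90)
  fv <- extract_features(tr50, tr90)
  expect_equal(fv$pA90[["spike_count"]], 4)
  expect_equal(fv$pA90[["latency"]], 12, tolerance = 2 * tr90$dt)
  expect_equal(fv$pA90[["isi_first"]], 38, tolerance = 2 * tr90$dt)
  expect_equal(fv$pA50[["spike_count"]], 0)
  expect_true(all(is.na(fv$pA50[setdiff(names(fv$pA50), "spike_count")])))
  # amplitude and half-height width of the stereotyped spike
  tr90b <- synth_trace(c(50, 120), amplitude = 80, width = 0.9,
                       amplitude_pA = 90)
  fvb <- extract_features(tr50, tr90b)
  slope <- 80 / 0.9
  expect_equal(fvb$pA90[["mean_amplitude"]], 80, tolerance = slope * tr90b$dt)
  expect_equal(fvb$pA90[["ap_width"]], 0.9, tolerance = 2 * tr90b$dt)
  # protocol mismatch is rejected
  bad <- tr90
  bad$protocol <- stimulus_protocol(90, pre_ms = 100, step_ms = 200, post_ms = 50)
  expect_error(extract_features(tr50, bad), "protocol mismatch")
})

test_that("feature extraction is dt-exact over many seeded fixture traces", {
  set.seed(101)
  for (rep in 1:200) {
    k <- sample(0:5, 1)
    times <- if (k > 0) sort(sample(seq(5, 190, by = 7), k)) else numeric(0)
    if (k > 1 && min(diff(times)) < 6.5) times <- times[c(TRUE, diff(times) >= 6.5)]
    amp <- runif(1, 60, 100)
    wid <- runif(1, 0.6, 1.4)
    tr <- synth_trace(times, amplitude = amp, width = wid, amplitude_pA = 90)
    ev <- detect_spikes(tr)
    expect_identical(nrow(ev), length(times))
    if (length(times)) {
      expect_equal(ev$onset_time, 50 + times, tolerance = 1.5 * tr$dt)
      expect_equal(mean(ev$peak_vm - ev$threshold_vm), amp,
                   tolerance = (amp / wid) * tr$dt + 1e-9)
    }
  }
})

make_targets <- function(means90, sds90,
                         means50 = NULL, sds50 = NULL) {
  nm <- c("spike_count", "latency", "threshold", "mean_amplitude",
          "fahp_amplitude", "abs_fahp_amplitude", "ap_width", "isi_first",
          "adaptation_index")
  full <- function(x) {
    out <- stats::setNames(rep(NA_real_, 9), nm)
    out[names(x)] <- x
    out
  }
  feature_targets(
    means = list(pA50 = full(means50), pA90 = full(means90)),
    sds = list(pA50 = full(sds50), pA90 = full(sds90)))
}

fv_from <- function(count90, extra90 = c(), count50 = 0) {
  nm <- c("spike_count", "latency", "threshold", "mean_amplitude",
          "fahp_amplitude", "abs_fahp_amplitude", "ap_width", "isi_first",
          "adaptation_index")
  v90 <- stats::setNames(rep(NA_real_, 9), nm)
  v90["spike_count"] <- count90
  v90[names(extra90)] <- extra90
  v50 <- stats::setNames(rep(NA_real_, 9), nm)
  v50["spike_count"] <- count50
  structure(list(pA50 = v50, pA90 = v90), class = "feature_vector")
}

test_that("fitness is deviation in SD units with a strict P < 2 criterion", {
  tg <- make_targets(means90 = c(spike_count = 4, latency = 20),
                     sds90 = c(spike_count = 1, latency = 5),
                     means50 = c(spike_count = 0), sds50 = c(spike_count = 0.5))
  # exact match: P = 0, valid
  r0 <- feature_fitness(fv_from(4, c(latency = 20)), tg)
  expect_equal(r0$P, 0)
  expect_true(r0$valid)
  # one feature at mean + 2 SD: P = 2, invalid (strict)
  r2 <- feature_fitness(fv_from(4, c(latency = 30)), tg)
  expect_equal(r2$P, 2)
  expect_false(r2$valid)
  # just inside the boundary is valid
  eps <- 1e-9
  r1 <- feature_fitness(fv_from(4, c(latency = 30 - 5 * eps / 2)), tg)
  expect_lt(r1$P, 2)
  expect_true(r1$valid)
  # non-spiking model gets the sentinel
  rs <- feature_fitness(fv_from(0), tg)
  expect_equal(rs$P, 6)
  expect_false(rs$valid)
  expect_true(rs$sentinel_applied)
})

test_that("fitness is scale-equivariant and monotone in deviations", {
  base_means <- c(spike_count = 4, latency = 20)
  # scaling one feature's deviation and SD together leaves F unchanged
  tg1 <- make_targets(base_means, c(spike_count = 1, latency = 5))
  tg2 <- make_targets(base_means, c(spike_count = 1, latency = 15))
  f1 <- feature_fitness(fv_from(4, c(latency = 25)), tg1)   # dev 5, sd 5
  f2 <- feature_fitness(fv_from(4, c(latency = 35)), tg2)   # dev 15, sd 15
  expect_equal(f1$F["latency", "pA90"], f2$F["latency", "pA90"])
  # P is non-decreasing as a single deviation grows
  P <- vapply(c(21, 24, 28, 33, 39), function(lat)
    feature_fitness(fv_from(4, c(latency = lat)), tg1)$P, numeric(1))
  expect_true(all(diff(P) >= 0))
  # undefined features are skipped rather than penalized
  r <- feature_fitness(fv_from(4), tg1)  # latency undefined in candidate
  expect_equal(r$P, 0)
})
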