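#' Surrogate channel kinetics for the granule-cell model family
#'
#' Parameterized Boltzmann/Hill gating kinetics for the fifteen channels of
#' the surrogate granule-cell family. Channels within a functional class
#' (delayed-rectifier-like potassium, high-voltage calcium, ...) are given
#' deliberately similar, partially overlapping kinetics so that class members
#' are degenerate: they can substitute for one another. All constants are
#' engineering defaults of this surrogate family, chosen so the baseline
#' models rest near -80 mV and fire a handful of spikes at 90 pA; they are
#' not measurements.
#'
#' @return Named list of [channel_spec()] objects.
#' @export
surrogate_channels <- function() {
  EK <- -90; ENa <- 60; ECa <- 120; Epas <- -80
  act <- function(...) gate_spec("activation", ...)
  inact <- function(...) gate_spec("inactivation", ...)
  cagate <- function(...) gate_spec("calcium_activation", ...)
  list(
    pas = channel_spec("pas", "leak", Epas, regions = "all"),
    Kir21 = channel_spec("Kir21", "K", EK, regions = "all", gates = list(
      act(v_half = -85, slope = -12, tau_base = 0.5))),
    na8st = channel_spec("na8st", "Na", ENa, regions = c("soma", "AIS"),
      gates = list(
        act(exponent = 3L, v_half = -42, slope = 6, tau_base = 0.04,
            tau_amp = 0.12, tau_v_half = -40, tau_sigma = 30),
        inact(v_half = -55, slope = -7, tau_base = 0.5, tau_amp = 6,
              tau_v_half = -65, tau_sigma = 20))),
    BK = channel_spec("BK", "K", EK, regions = c("soma", "AIS"), gates = list(
      act(v_half = -5, slope = 11, tau_base = 0.3, tau_amp = 1.5,
          tau_v_half = -20, tau_sigma = 25),
      cagate(tau_base = 1, ca_half = 0.8, hill_coeff = 2))),
    SK = channel_spec("SK", "K", EK, regions = c("soma", "dendrite"),
      gates = list(cagate(tau_base = 1.5, ca_half = 1.2, hill_coeff = 2))),
    Kv11 = channel_spec("Kv11", "K", EK, regions = c("soma", "AIS"),
      gates = list(act(v_half = -10, slope = 7, tau_base = 0.8, tau_amp = 4,
                       tau_v_half = -25, tau_sigma = 25))),
    Kv14 = channel_spec("Kv14", "K", EK,
      regions = c("soma", "AIS", "dendrite"), gates = list(
        act(v_half = -10, slope = 7, tau_base = 0.5, tau_amp = 2,
            tau_v_half = -28, tau_sigma = 25),
        inact(v_half = -65, slope = -6, tau_base = 8, tau_amp = 25,
              tau_v_half = -70, tau_sigma = 20))),
    Kv21 = channel_spec("Kv21", "K", EK, regions = "soma", gates = list(
      act(exponent = 2L, v_half = -10, slope = 7, tau_base = 0.8,
          tau_amp = 4, tau_v_half = -25, tau_sigma = 25))),
    Kv34 = channel_spec("Kv34", "K", EK, regions = "AIS", gates = list(
      act(v_half = -8, slope = 6, tau_base = 0.3, tau_amp = 1,
          tau_v_half = -18, tau_sigma = 20))),
    Kv42 = channel_spec("Kv42", "K", EK, regions = "soma", gates = list(
      act(v_half = -10, slope = 7, tau_base = 0.5, tau_amp = 2,
          tau_v_half = -30, tau_sigma = 25),
      inact(v_half = -70, slope = -6, tau_base = 10, tau_amp = 30,
            tau_v_half = -75, tau_sigma = 20))),
    Kv723 = channel_spec("Kv723", "K", EK, regions = "soma", gates = list(
      act(v_half = -12, slope = 7, tau_base = 4, tau_amp = 20,
          tau_v_half = -30, tau_sigma = 25))),
    Cav22 = channel_spec("Cav22", "Ca", ECa, feeds_ca_pool = TRUE,
      regions = c("soma", "AIS", "dendrite"), gates = list(
        act(exponent = 2L, v_half = -18, slope = 7, tau_base = 0.3,
            tau_amp = 1, tau_v_half = -25, tau_sigma = 25))),
    Cav12 = channel_spec("Cav12", "Ca", ECa, feeds_ca_pool = TRUE,
      regions = c("soma", "dendrite"), gates = list(
        act(exponent = 2L, v_half = -12, slope = 6, tau_base = 0.4,
            tau_amp = 1, tau_v_half = -20, tau_sigma = 25))),
    Cav13 = channel_spec("Cav13", "Ca", ECa, feeds_ca_pool = TRUE,
      regions = c("soma", "dendrite"), gates = list(
        act(exponent = 2L, v_half = -20, slope = 7, tau_base = 0.4,
            tau_amp = 1, tau_v_half = -25, tau_sigma = 25))),
    Cav32 = channel_spec("Cav32", "Ca", ECa, feeds_ca_pool = TRUE,
      regions = c("soma", "AIS", "dendrite"), gates = list(
        act(exponent = 2L, v_half = -38, slope = 6.5, tau_base = 0.5, tau_amp = 2,
            tau_v_half = -45, tau_sigma = 20),
        inact(v_half = -75, slope = -6, tau_base = 10, tau_amp = 40,
              tau_v_half = -80, tau_sigma = 20)))
  )
}

# Shared passive backbone of the surrogate family.
surrogate_compartments <- function() {
  list(compartment_spec("soma", area = 2e-5, capacitance = 1),
       compartment_spec("AIS", area = 2e-6, capacitance = 1,
                        parent = "soma", g_axial = 0.05),
       compartment_spec("dendrite", area = 8e-5, capacitance = 1,
                        parent = "soma", g_axial = 0.03))
}

surrogate_ca_pool <- function() {
  # influx per compartment scaled inversely with area (smaller compartment,
  # smaller submembrane volume); order soma, AIS, dendrite
  calcium_pool_spec(influx_factor = c(0.5, 5, 0.125), tau_removal = 15,
                    ca_rest = 0.05)
}

#' Baseline surrogate granule-cell models
#'
#' Builds the three baseline models of the surrogate family. The 5-channel
#' roster is exactly \{pas, Kir21, na8st, BK, Cav22\} (9 region-resolved
#' parameters); the 9-channel roster adds Kv21, Kv34, Kv42 and Kv723 (13
#' parameters); the 15-channel roster further adds Cav12, Cav13, Cav32,
#' Kv11, Kv14 and SK (27 parameters). Within each functional class the class
#' total conductance is conserved across rosters and split among the members
#' present, so reduced models concentrate the same machinery in fewer
#' channels. The `pas` and `Kir21` entries are frozen in all models.
#'
#' @return Named list of [neuron_config()]s: `gc5`, `gc9`, `gc15`.
#' @export
make_baseline_models <- function() {
  ch <- surrogate_channels()
  comps <- surrogate_compartments()
  pool <- surrogate_ca_pool()
  rosters <- list(
    gc5 = c("pas", "Kir21", "na8st", "BK", "Cav22"),
    gc9 = c("pas", "Kir21", "na8st", "BK", "Cav22",
            "Kv21", "Kv34", "Kv42", "Kv723"),
    gc15 = names(ch)
  )
  tables <- list(
    gc5 = c("pas@all" = 0.015, "Kir21@all" = 0.01,
            "na8st@soma" = 40, "na8st@AIS" = 150,
            "BK@soma" = 30, "BK@AIS" = 30,
            "Cav22@soma" = 2.5, "Cav22@AIS" = 2.5, "Cav22@dendrite" = 0.5),
    gc9 = c("pas@all" = 0.015, "Kir21@all" = 0.01,
            "na8st@soma" = 40, "na8st@AIS" = 150,
            "BK@soma" = 12, "BK@AIS" = 20,
            "Cav22@soma" = 2.5, "Cav22@AIS" = 2.5, "Cav22@dendrite" = 0.5,
            "Kv21@soma" = 8, "Kv34@AIS" = 10, "Kv42@soma" = 5,
            "Kv723@soma" = 5),
    gc15 = c("pas@all" = 0.015, "Kir21@all" = 0.01,
             "na8st@soma" = 40, "na8st@AIS" = 150,
             "BK@soma" = 7, "BK@AIS" = 12,
             "Cav22@soma" = 1.0, "Cav22@AIS" = 1.2, "Cav22@dendrite" = 0.2,
             "Kv21@soma" = 5, "Kv34@AIS" = 8, "Kv42@soma" = 3,
             "Kv723@soma" = 3,
             "Kv11@soma" = 4, "Kv11@AIS" = 5,
             "Kv14@soma" = 3, "Kv14@AIS" = 5, "Kv14@dendrite" = 0.5,
             "SK@soma" = 2, "SK@dendrite" = 0.2,
             "Cav12@soma" = 0.5, "Cav12@dendrite" = 0.1,
             "Cav13@soma" = 0.5, "Cav13@dendrite" = 0.1,
             "Cav32@soma" = 0.25, "Cav32@AIS" = 0.4, "Cav32@dendrite" = 0.05)
  )
  out <- lapply(names(rosters), function(nm) {
    neuron_config(comps, unname(ch[rosters[[nm]]]), pool, tables[[nm]])
  })
  names(out) <- names(rosters)
  out
}

#' Synthesize a voltage trace with known ground truth
#'
#' Builds a trace for the standard protocol with stereotyped piecewise-linear
#' spikes superimposed on a resting level: from each onset the potential
#' rises linearly to `rest + amplitude`, falls linearly to the fAHP trough
#' `rest - fahp`, then relaxes back to rest over 3 ms. Up- and down-stroke
#' slopes are equal and chosen so the half-height width equals `width`.
#' Spikes must be separated by at least `width + 5` ms.
#'
#' @param spike_times spike onsets in ms after stimulus onset (must lie in
#'   the stimulus window).
#' @param amplitude spike height above rest (mV).
#' @param width half-height width (ms, >= 2 dt).
#' @param fahp trough depth below rest (mV, >= 0).
#' @param rest resting level (mV).
#' @param noise_sd Gaussian noise SD (mV) added pointwise.
#' @param amplitude_pA nominal stimulus amplitude recorded in the protocol.
#' @param dt sample interval (ms).
#' @param seed seed for the noise.
#' @return A `voltage_trace` with a single somatic column.
#' @export
synth_trace <- function(spike_times, amplitude = 80, width = 0.9, fahp = 10,
                        rest = -80, noise_sd = 0, amplitude_pA = 90,
                        dt = 0.025, seed = 1) {
  pre <- 50; stim <- 200; post <- 50
  stopifnot(width >= 2 * dt, fahp >= 0, amplitude > 0)
  spike_times <- sort(spike_times)
  if (length(spike_times)) {
    stopifnot(all(spike_times >= 0), all(spike_times < stim))
    if (length(spike_times) > 1 &&
        any(diff(spike_times) < width + 5))
      stop("overlapping spikes: separation below width + 5 ms")
  }
  n <- round((pre + stim + post) / dt) + 1L
  time <- (seq_len(n) - 1L) * dt
  vm <- rep(rest, n)
  slope <- amplitude / width  # equal up/down slopes give half-height width
  for (t0 in pre + spike_times) {
    t_peak <- t0 + amplitude / slope
    t_trough <- t_peak + (amplitude + fahp) / slope
    t_back <- t_trough + 3
    seg <- which(time >= t0 & time <= t_back + dt)
    for (i in seg) {
      tt <- time[i]
      vm[i] <- if (tt <= t_peak) rest + slope * (tt - t0)
      else if (tt <= t_trough) rest + amplitude - slope * (tt - t_peak)
      else if (tt <= t_back) rest - fahp + fahp * (tt - t_trough) / 3
      else rest
    }
  }
  if (noise_sd > 0)
    vm <- vm + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  vmm <- matrix(vm, ncol = 1, dimnames = list(NULL, "soma"))
  structure(list(dt = dt, time = time, vm = vmm, ca = NULL, currents = NULL,
                 onset_index = round(pre / dt) + 1L, vrest = rest,
                 protocol = stimulus_protocol(amplitude_pA, pre, stim, post)),
            class = "voltage_trace")
}
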