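#' Gating-variable specification
#'
#' A gate is one Hodgkin-Huxley-style state variable of an ion channel.
#' Voltage gates have a Boltzmann steady state
#' \eqn{x_\infty(V) = 1/(1 + \exp(-(V - V_{1/2})/k))} (a negative slope
#' \eqn{k} yields a gate that closes with depolarisation, as for
#' inactivation or inward rectification). Calcium gates have a Hill steady
#' state \eqn{x_\infty = [Ca]^h / ([Ca]^h + K_{1/2}^h)}. All gates share a
#' Gaussian-bell voltage-dependent time constant
#' \eqn{\tau(V) = \max(\tau_{min}, \tau_{base} + \tau_{amp}
#' \exp(-(V-V_\tau)^2 / 2\sigma_\tau^2))}.
#'
#' @param role one of `"activation"`, `"inactivation"`, `"calcium_activation"`.
#' @param exponent non-negative integer power applied to the gate state.
#' @param v_half,slope Boltzmann midpoint (mV) and slope (mV, nonzero, signed).
#' @param tau_base,tau_amp,tau_v_half,tau_sigma bell time-constant parameters
#'   (ms, ms, mV, mV > 0).
#' @param ca_half,hill_coeff Hill midpoint (uM) and coefficient (> 0); calcium
#'   gates only.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(role = c("activation", "inactivation", "calcium_activation"),
                      exponent = 1L, v_half = -40, slope = 5,
                      tau_base = 1, tau_amp = 0, tau_v_half = -40, tau_sigma = 15,
                      ca_half = NULL, hill_coeff = NULL) {
  role <- match.arg(role)
  stopifnot(exponent >= 0, exponent == round(exponent),
            is.finite(v_half), is.finite(slope), slope != 0,
            tau_base >= 0, tau_amp >= 0, tau_sigma > 0)
  if (role == "calcium_activation") {
    if (is.null(ca_half) || is.null(hill_coeff))
      stop("calcium_activation gates require `ca_half` and `hill_coeff`")
    stopifnot(ca_half > 0, hill_coeff > 0)
  } else {
    ca_half <- NA_real_
    hill_coeff <- NA_real_
  }
  structure(list(role = role, exponent = as.integer(exponent),
                 v_half = v_half, slope = slope,
                 tau_base = tau_base, tau_amp = tau_amp,
                 tau_v_half = tau_v_half, tau_sigma = tau_sigma,
                 ca_half = ca_half, hill_coeff = hill_coeff),
            class = "gate_spec")
}

#' Steady-state open fraction of a gate
#'
#' @param gate a [gate_spec()].
#' @param vm membrane potential (mV).
#' @param ca calcium concentration (uM); required iff the gate is
#'   calcium-activated.
#' @return Open fraction in `[0, 1]`.
#' @export
gate_steady_state <- function(gate, vm, ca = NULL) {
  stopifnot(inherits(gate, "gate_spec"))
  if (gate$role == "calcium_activation") {
    if (is.null(ca))
      stop("calcium-activated gate evaluated without a calcium concentration")
    ifelse(ca <= 0, 0, ca^gate$hill_coeff /
             (ca^gate$hill_coeff + gate$ca_half^gate$hill_coeff))
  } else {
    1 / (1 + exp(-(vm - gate$v_half) / gate$slope))
  }
}

#' Voltage-dependent time constant of a gate
#'
#' `tau(vm) = max(tau_min, tau_base + tau_amp * bell(vm))` where the bell is a
#' Gaussian with unit peak at `tau_v_half` and width `tau_sigma`.
#'
#' @inheritParams gate_steady_state
#' @param tau_min lower floor in ms (bounds solver stiffness).
#' @return Time constant in ms, strictly positive.
#' @export
gate_time_constant <- function(gate, vm, tau_min = 0.05) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(vm)), tau_min > 0)
  z <- (vm - gate$tau_v_half) / gate$tau_sigma
  pmax(tau_min, gate$tau_base + gate$tau_amp * exp(-0.5 * z^2))
}

#' Ion-channel specification
#'
#' @param name channel identifier, unique within a model (e.g. `"na8st"`).
#' @param ion one of `"Na"`, `"K"`, `"Ca"`, `"leak"`.
#' @param reversal reversal potential (mV).
#' @param gates list of [gate_spec()] objects (possibly empty for ohmic leak).
#' @param feeds_ca_pool does this channel's current feed the calcium pool?
#'   Only permitted for `ion = "Ca"`.
#' @param regions character vector of region groups in which the channel is
#'   expressed; each entry is a compartment name or `"all"`, and each entry
#'   contributes one conductance-density parameter.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, ion = c("Na", "K", "Ca", "leak"), reversal,
                         gates = list(), feeds_ca_pool = FALSE,
                         regions = "soma") {
  ion <- match.arg(ion)
  stopifnot(is.character(name), nzchar(name), is.finite(reversal),
            is.character(regions), length(regions) >= 1,
            !anyDuplicated(regions))
  if (feeds_ca_pool && ion != "Ca")
    stop("feeds_ca_pool requires ion = 'Ca' (channel ", name, ")")
  for (g in gates) stopifnot(inherits(g, "gate_spec"))
  structure(list(name = name, ion = ion, reversal = reversal, gates = gates,
                 feeds_ca_pool = isTRUE(feeds_ca_pool), regions = regions),
            class = "channel_spec")
}

#' Create an artificial isoform of a channel
#'
#' Returns a copy of `channel` under a new name in which every gate
#' time-constant parameter (`tau_base` and `tau_amp`) is multiplied by an
#' independent uniform factor on `[0, 2)`, emulating an isoform with altered
#' dynamics. Steady-state parameters (`v_half`, `slope`, Hill parameters),
#' ion, reversal potential and regions are unchanged.
#'
#' @param channel a [channel_spec()] with at least one gate.
#' @param rng_seed integer seed; the same seed reproduces the same isoform.
#' @param name name of the new channel; default appends `"_iso<seed>"`.
#' @return A new `channel_spec`.
#' @export
make_isoform <- function(channel, rng_seed, name = NULL) {
  stopifnot(inherits(channel, "channel_spec"), length(channel$gates) >= 1)
  if (is.null(name)) name <- paste0(channel$name, "_iso", rng_seed)
  iso <- channel
  iso$name <- name
  iso$gates <- withr::with_seed(rng_seed, lapply(channel$gates, function(g) {
    g$tau_base <- g$tau_base * stats::runif(1, 0, 2)
    g$tau_amp <- g$tau_amp * stats::runif(1, 0, 2)
    g
  }))
  iso
}
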