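#' Current-clamp stimulus protocol
#'
#' A square somatic current step flanked by silent segments. The standard
#' feature-extraction protocol is a 50 ms prerun, a 200 ms step of 50 or
#' 90 pA, and a 50 ms tail.
#'
#' @param amplitude step amplitude (pA).
#' @param pre_ms,step_ms,post_ms segment durations (ms).
#' @param site injected compartment name.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude, pre_ms = 50, step_ms = 200,
                              post_ms = 50, site = "soma") {
  stopifnot(is.finite(amplitude), pre_ms >= 0, step_ms > 0, post_ms >= 0)
  structure(list(amplitude = amplitude, pre_ms = pre_ms, step_ms = step_ms,
                 post_ms = post_ms, site = site),
            class = "stimulus_protocol")
}

#' Solver options for the fixed-step integrator
#'
#' @param dt time step (ms, must be <= 0.1).
#' @param tau_min floor on gate time constants (ms); bounds stiffness.
#' @param settle_ms unstimulated settle-in before the protocol; the settled
#'   somatic potential defines the resting potential.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(dt = 0.025, tau_min = 0.05, settle_ms = 500) {
  stopifnot(dt > 0, dt <= 0.1, tau_min > 0, settle_ms >= 0)
  structure(list(dt = dt, tau_min = tau_min, settle_ms = settle_ms),
            class = "solver_options")
}

#' Prepare a reusable simulation session for one model's kinetics
#'
#' Builds the compiled gate tables once; repeated simulations that differ
#' only in conductance densities (population sampling, searches, walks) then
#' reuse the session. Kinetic parameters and `dt` are baked in.
#'
#' @param config a [neuron_config()].
#' @param solver a [solver_options()].
#' @return An opaque `model_session` object.
#' @export
model_session <- function(config, solver = solver_options()) {
  flat <- flatten_model(config)
  ptr <- .cp_build_session(flat$model, solver$dt, solver$tau_min)
  structure(list(ptr = ptr, flat = flat, solver = solver, config = config),
            class = "model_session")
}

# Expand a full conductance-table vector to the per-placement density order
# used by the compiled model (placements reference table entries by index, so
# the table vector itself is what the C++ side consumes).
session_densities <- function(session, table = NULL) {
  if (is.null(table)) table <- session$config$conductance_table
  stopifnot(length(table) == length(session$config$conductance_table))
  as.numeric(table)
}

#' Run a prepared session at one or more step amplitudes
#'
#' The settle-in is shared across amplitudes. Densities may be overridden by
#' passing a full conductance `table` (same keys/order as the config's),
#' which is how population sampling reuses one session.
#'
#' @param session a [model_session()].
#' @param amplitudes step amplitudes (pA).
#' @param table optional replacement conductance table (named as the
#'   config's table).
#' @param pre_ms,step_ms,post_ms protocol segments (ms).
#' @param record_currents record per-placement ionic currents?
#' @param record_full record all compartments' Vm and Ca (otherwise somatic
#'   Vm only)?
#' @param site stimulated compartment.
#' @return List of `voltage_trace` objects, one per amplitude.
#' @export
session_simulate <- function(session, amplitudes, table = NULL,
                             pre_ms = 50, step_ms = 200, post_ms = 50,
                             record_currents = FALSE, record_full = TRUE,
                             site = "soma") {
  dens <- session_densities(session, table)
  inj_comp <- match(site, session$flat$comp_names) - 1L
  if (is.na(inj_comp)) stop("unknown stimulation site: ", site)
  raw <- .cp_simulate(session$ptr, dens, as.numeric(amplitudes),
                      pre_ms, step_ms, post_ms, session$solver$settle_ms,
                      inj_comp, record_currents, record_full)
  dt <- session$solver$dt
  lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    vm <- r$vm
    colnames(vm) <- if (record_full) session$flat$comp_names else "soma"
    ca <- if (record_full) {
      colnames(r$ca) <- session$flat$comp_names
      r$ca
    } else NULL
    cur <- if (record_currents) {
      colnames(r$currents) <- session$flat$placement_labels
      r$currents
    } else NULL
    structure(list(dt = dt,
                   time = (seq_len(nrow(vm)) - 1L) * dt,
                   vm = vm, ca = ca, currents = cur,
                   onset_index = r$onset_index,
                   vrest = r$vrest,
                   protocol = stimulus_protocol(amplitudes[i], pre_ms,
                                                step_ms, post_ms, site)),
              class = "voltage_trace")
  })
}

#' Simulate a current-clamp protocol
#'
#' Integrates the model with a fixed-step scheme (exponential-Euler gate
#' updates, implicit voltage update over the coupled compartments) after an
#' unstimulated settle-in that defines the resting state.
#'
#' @param config a [neuron_config()].
#' @param protocol a [stimulus_protocol()].
#' @param solver a [solver_options()].
#' @param record_currents also record per-channel, per-compartment ionic
#'   currents (nA)?
#' @return A `voltage_trace`: time base (ms, origin at protocol start, with
#'   the stimulus-onset sample index recorded), per-compartment membrane
#'   potential (mV) and calcium (uM), and optionally per-channel currents.
#' @export
simulate_current_clamp <- function(config, protocol, solver = solver_options(),
                                   record_currents = FALSE) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(solver, "solver_options"))
  session <- model_session(config, solver)
  session_simulate(session, protocol$amplitude,
                   pre_ms = protocol$pre_ms, step_ms = protocol$step_ms,
                   post_ms = protocol$post_ms,
                   record_currents = record_currents,
                   site = protocol$site)[[1]]
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace>: ", nrow(x$vm), " samples at dt = ", x$dt, " ms (",
      utils::tail(x$time, 1), " ms), Vrest = ", round(x$vrest, 2), " mV, ",
      "stimulus ", x$protocol$amplitude, " pA\n", sep = "")
  invisible(x)
}

#' Somatic membrane potential of a trace
#' @param trace a `voltage_trace`.
#' @return Numeric vector (mV).
#' @export
soma_vm <- function(trace) trace$vm[, "soma"]

#' Decompose recorded currents into inward/outward fractional contributions
#'
#' At each time step, the inward fraction of a channel is its current divided
#' by the summed negative (inward) currents, as a percentage; likewise for
#' outward over the positive currents. Steps where a sign class carries no
#' current report `NA` for that class.
#'
#' @param trace a `voltage_trace` simulated with `record_currents = TRUE`.
#' @return List with matrices `inward_pct` and `outward_pct` (rows = time
#'   steps, columns = channel placements; percentages summing to 100 where
#'   defined) and the corresponding `total_inward`/`total_outward` (nA).
#' @export
decompose_currents <- function(trace) {
  if (is.null(trace$currents))
    stop("trace lacks per-channel currents; simulate with record_currents = TRUE")
  cur <- trace$currents
  inward <- pmin(cur, 0)
  outward <- pmax(cur, 0)
  tot_in <- rowSums(inward)
  tot_out <- rowSums(outward)
  in_pct <- inward / ifelse(tot_in == 0, NA_real_, tot_in) * 100
  out_pct <- outward / ifelse(tot_out == 0, NA_real_, tot_out) * 100
  list(inward_pct = in_pct, outward_pct = out_pct,
       total_inward = tot_in, total_outward = tot_out)
}

#' Write a voltage trace to CSV
#'
#' Columns: `time_ms`, `Vm_<compartment>`, `Ca_<compartment>`, and
#' `I_<placement>` when currents were recorded.
#'
#' @param trace a `voltage_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = trace$time)
  for (cn in colnames(trace$vm)) df[[paste0("Vm_", cn)]] <- trace$vm[, cn]
  if (!is.null(trace$ca))
    for (cn in colnames(trace$ca)) df[[paste0("Ca_", cn)]] <- trace$ca[, cn]
  if (!is.null(trace$currents))
    for (cn in colnames(trace$currents))
      df[[paste0("I_", cn)]] <- trace$currents[, cn]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a voltage trace written by [write_trace()]
#'
#' @param path CSV file path.
#' @param onset_index stimulus-onset sample index (not stored in the CSV).
#' @return A `voltage_trace` (without a protocol attached unless given).
#' @param protocol optional [stimulus_protocol()] to attach.
#' @export
read_trace <- function(path, onset_index = NULL, protocol = NULL) {
  df <- utils::read.csv(path)
  dt <- df$time_ms[2] - df$time_ms[1]
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_"), names(df), value = TRUE)
    if (!length(cols)) return(NULL)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0("^", prefix, "_"), "", cols)
    m
  }
  vm <- pick("Vm")
  structure(list(dt = dt, time = df$time_ms, vm = vm, ca = pick("Ca"),
                 currents = pick("I"),
                 onset_index = onset_index,
                 vrest = vm[1, "soma"],
                 protocol = protocol),
            class = "voltage_trace")
}
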