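#' Compartment specification
#'
#' Isopotential membrane region. The coupling graph must be a tree rooted at
#' the (single) soma; each non-root compartment names its parent and the
#' axial conductance to it.
#'
#' @param name one of `"soma"`, `"AIS"`, `"dendrite"`.
#' @param area membrane area (cm^2, > 0).
#' @param capacitance specific capacitance (uF/cm^2, > 0).
#' @param parent name of the parent compartment, or `NA` for the soma.
#' @param g_axial axial conductance to the parent (uS); ignored for the soma.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(name, area, capacitance = 1, parent = NA_character_,
                             g_axial = NA_real_) {
  stopifnot(name %in% c("soma", "AIS", "dendrite"), area > 0, capacitance > 0)
  if (!is.na(parent)) stopifnot(is.finite(g_axial), g_axial > 0)
  structure(list(name = name, area = area, capacitance = capacitance,
                 parent = parent, g_axial = g_axial),
            class = "compartment_spec")
}

#' Calcium pool specification
#'
#' One first-order intracellular calcium pool per compartment:
#' `d[Ca]/dt = influx - ([Ca] - ca_rest) / tau_removal`, where the influx is
#' proportional to the total inward calcium current in that compartment.
#'
#' @param influx_factor uM of calcium per nA.ms of inward calcium current.
#' @param tau_removal removal time constant (ms, > 0).
#' @param ca_rest resting concentration (uM, > 0).
#' @return An object of class `calcium_pool_spec`.
#' @export
calcium_pool_spec <- function(influx_factor = 0.1, tau_removal = 20,
                              ca_rest = 0.05) {
  stopifnot(influx_factor >= 0, tau_removal > 0, ca_rest > 0)
  structure(list(influx_factor = influx_factor, tau_removal = tau_removal,
                 ca_rest = ca_rest),
            class = "calcium_pool_spec")
}

#' Neuron model configuration
#'
#' Binds compartments, a channel roster, a calcium pool and a
#' region-resolved conductance table into one simulatable model. The
#' conductance table has one entry per (channel, region-group) pair; the keys
#' of frozen entries (by default every `pas` and `Kir21` entry, the passive
#' backbone) are excluded from sampling and search.
#'
#' @param compartments list of [compartment_spec()]s; exactly one soma.
#' @param channels list of [channel_spec()]s with unique names.
#' @param ca_pool a [calcium_pool_spec()].
#' @param conductance_table named numeric vector of densities (mS/cm^2,
#'   >= 0) keyed `"channel@region"`, covering every (channel, region) the
#'   roster declares.
#' @param frozen_parameters character vector of frozen keys; defaults to all
#'   `pas` and `Kir21` entries.
#' @return An object of class `neuron_config`.
#' @export
neuron_config <- function(compartments, channels, ca_pool, conductance_table,
                          frozen_parameters = NULL) {
  stopifnot(length(compartments) >= 1, inherits(ca_pool, "calcium_pool_spec"))
  comp_names <- vapply(compartments, function(x) x$name, character(1))
  if (sum(comp_names == "soma") != 1) stop("exactly one soma required")
  if (anyDuplicated(comp_names)) stop("duplicate compartment names")
  for (cp in compartments) {
    stopifnot(inherits(cp, "compartment_spec"))
    if (!is.na(cp$parent) && !(cp$parent %in% comp_names))
      stop("unknown parent compartment: ", cp$parent)
    if (cp$name == "soma" && !is.na(cp$parent)) stop("soma must be the root")
    if (cp$name != "soma" && is.na(cp$parent))
      stop("non-soma compartment ", cp$name, " must have a parent")
  }
  ch_names <- vapply(channels, function(x) x$name, character(1))
  if (anyDuplicated(ch_names)) stop("duplicate channel names")
  expected <- unlist(lapply(channels, function(ch) {
    for (r in ch$regions)
      if (!(r == "all" || r %in% comp_names))
        stop("channel ", ch$name, " declares unknown region ", r)
    paste0(ch$name, "@", ch$regions)
  }))
  if (!setequal(names(conductance_table), expected))
    stop("conductance_table keys must match the declared (channel, region) pairs; ",
         "missing: ", paste(setdiff(expected, names(conductance_table)), collapse = ", "),
         "; extra: ", paste(setdiff(names(conductance_table), expected), collapse = ", "))
  if (any(conductance_table < 0)) stop("conductance densities must be >= 0")
  if (is.null(frozen_parameters))
    frozen_parameters <- expected[sub("@.*", "", expected) %in% c("pas", "Kir21")]
  if (!all(frozen_parameters %in% expected))
    stop("frozen key not in conductance table: ",
         paste(setdiff(frozen_parameters, expected), collapse = ", "))
  structure(list(compartments = compartments, channels = channels,
                 ca_pool = ca_pool,
                 conductance_table = conductance_table[expected],
                 frozen_parameters = frozen_parameters),
            class = "neuron_config")
}

#' @export
print.neuron_config <- function(x, ...) {
  cat("<neuron_config>: ", length(x$channels), " channels, ",
      length(x$compartments), " compartments, ",
      length(x$conductance_table), " conductance parameters (",
      length(x$frozen_parameters), " frozen)\n", sep = "")
  cat("  channels:", paste(vapply(x$channels, `[[`, character(1), "name"),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Names of the free (sampled/searched) parameters of a model
#'
#' @param config a [neuron_config()].
#' @return Character vector of `"channel@region"` keys, in table order.
#' @export
free_parameters <- function(config) {
  setdiff(names(config$conductance_table), config$frozen_parameters)
}

#' Extract the free parameter vector of a model
#'
#' @param config a [neuron_config()].
#' @return Named numeric vector (mS/cm^2) over [free_parameters()].
#' @export
parameter_vector <- function(config) {
  config$conductance_table[free_parameters(config)]
}

#' Apply a (partial) parameter vector to a model configuration
#'
#' Returns a copy of `config` with the listed free densities replaced. Frozen
#' entries may not be set; unknown keys are an error.
#'
#' @param config a [neuron_config()].
#' @param vector named numeric vector over a subset of [free_parameters()].
#' @return The updated `neuron_config`.
#' @export
apply_parameters <- function(config, vector) {
  stopifnot(inherits(config, "neuron_config"), is.numeric(vector))
  keys <- names(vector)
  if (is.null(keys) || any(!nzchar(keys))) stop("parameter vector must be named")
  unknown <- setdiff(keys, names(config$conductance_table))
  if (length(unknown)) stop("unknown parameter key: ", paste(unknown, collapse = ", "))
  frozen <- intersect(keys, config$frozen_parameters)
  if (length(frozen)) stop("cannot set frozen parameter: ", paste(frozen, collapse = ", "))
  if (any(vector < 0)) stop("conductance densities must be >= 0")
  config$conductance_table[keys] <- vector
  config
}

# ---- internal: flatten a neuron_config for the compiled integrator ----------

# Expands region groups to per-compartment channel placements. Each placement
# records which conductance-table entry scales it, so a density vector in
# table order drives the compiled model directly.
flatten_model <- function(config) {
  comp_names <- vapply(config$compartments, `[[`, character(1), "name")
  parent <- vapply(config$compartments, function(cp) {
    if (is.na(cp$parent)) -1L else match(cp$parent, comp_names) - 1L
  }, integer(1))
  comps <- list(
    area = vapply(config$compartments, `[[`, numeric(1), "area"),
    capacitance = vapply(config$compartments, `[[`, numeric(1), "capacitance"),
    parent = parent,
    g_axial = vapply(config$compartments, function(cp)
      if (is.na(cp$g_axial)) 0 else cp$g_axial, numeric(1))
  )
  keys <- names(config$conductance_table)
  placements <- list()
  placement_labels <- character(0)
  role_code <- c(activation = 0L, inactivation = 1L, calcium_activation = 2L)
  for (ch in config$channels) {
    gates <- lapply(ch$gates, function(g) {
      list(role = role_code[[g$role]], exponent = g$exponent,
           v_half = g$v_half, slope = g$slope,
           tau_base = g$tau_base, tau_amp = g$tau_amp,
           tau_v_half = g$tau_v_half, tau_sigma = g$tau_sigma,
           ca_half = if (is.na(g$ca_half)) 1 else g$ca_half,
           hill = if (is.na(g$hill_coeff)) 1 else g$hill_coeff)
    })
    for (r in ch$regions) {
      key <- paste0(ch$name, "@", r)
      param <- match(key, keys) - 1L
      target <- if (r == "all") comp_names else r
      for (cn in target) {
        placements[[length(placements) + 1L]] <- list(
          comp = match(cn, comp_names) - 1L, param = param,
          erev = ch$reversal, feeds_ca = ch$feeds_ca_pool, gates = gates)
        placement_labels <- c(placement_labels, paste0(ch$name, ".", cn))
      }
    }
  }
  pool <- config$ca_pool
  list(model = list(compartments = comps,
                    ca_pool = list(influx_factor = pool$influx_factor,
                                   tau_removal = pool$tau_removal,
                                   ca_rest = pool$ca_rest),
                    placements = placements),
       comp_names = comp_names,
       placement_labels = placement_labels)
}
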