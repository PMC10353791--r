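SCHEMA_VERSION <- "1.0"

# Deterministic seed splitting: one global seed expands into per-component
# child seeds, so adding consumers never shifts another component's stream.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index) %% 2147483647)
}

gate_to_list <- function(g) {
  out <- list(role = g$role, exponent = g$exponent, v_half = g$v_half,
              slope = g$slope, tau_base = g$tau_base, tau_amp = g$tau_amp,
              tau_v_half = g$tau_v_half, tau_sigma = g$tau_sigma)
  if (g$role == "calcium_activation") {
    out$ca_half <- g$ca_half
    out$hill_coeff <- g$hill_coeff
  }
  out
}

#' Write a model configuration to a structured text file
#'
#' Serializes a [neuron_config()] (compartments, channels and gates,
#' calcium pool, conductance table, frozen set) to YAML with a schema
#' version. [read_model_config()] restores it exactly.
#'
#' @param config a [neuron_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "neuron_config"))
  obj <- list(
    schema_version = SCHEMA_VERSION,
    compartments = lapply(config$compartments, function(cp)
      list(name = cp$name, area = cp$area, capacitance = cp$capacitance,
           parent = if (is.na(cp$parent)) NULL else cp$parent,
           g_axial = if (is.na(cp$g_axial)) NULL else cp$g_axial)),
    channels = lapply(config$channels, function(ch)
      list(name = ch$name, ion = ch$ion, reversal = ch$reversal,
           feeds_ca_pool = ch$feeds_ca_pool, regions = as.list(ch$regions),
           gates = lapply(ch$gates, gate_to_list))),
    ca_pool = list(influx_factor = config$ca_pool$influx_factor,
                   tau_removal = config$ca_pool$tau_removal,
                   ca_rest = config$ca_pool$ca_rest),
    conductance_table = as.list(config$conductance_table),
    frozen_parameters = as.list(config$frozen_parameters))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

#' Read a model configuration written by [write_model_config()]
#'
#' Schema-validated: unknown keys are rejected and the schema version must
#' match.
#'
#' @param path YAML file.
#' @return A [neuron_config()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- yaml::read_yaml(path)
  check_keys(obj, c("schema_version", "compartments", "channels", "ca_pool",
                    "conductance_table", "frozen_parameters"), "model config")
  if (!identical(obj$schema_version, SCHEMA_VERSION))
    stop("unsupported schema version: ", obj$schema_version)
  comps <- lapply(obj$compartments, function(cp) {
    check_keys(cp, c("name", "area", "capacitance", "parent", "g_axial"),
               "compartment")
    compartment_spec(cp$name, cp$area, cp$capacitance,
                     parent = cp$parent %||% NA_character_,
                     g_axial = cp$g_axial %||% NA_real_)
  })
  chans <- lapply(obj$channels, function(ch) {
    check_keys(ch, c("name", "ion", "reversal", "feeds_ca_pool", "regions",
                     "gates"), "channel")
    gates <- lapply(ch$gates, function(g) {
      check_keys(g, c("role", "exponent", "v_half", "slope", "tau_base",
                      "tau_amp", "tau_v_half", "tau_sigma", "ca_half",
                      "hill_coeff"), "gate")
      gate_spec(g$role, g$exponent, g$v_half, g$slope, g$tau_base, g$tau_amp,
                g$tau_v_half, g$tau_sigma, ca_half = g$ca_half,
                hill_coeff = g$hill_coeff)
    })
    channel_spec(ch$name, ch$ion, ch$reversal, gates = gates,
                 feeds_ca_pool = isTRUE(ch$feeds_ca_pool),
                 regions = unlist(ch$regions))
  })
  check_keys(obj$ca_pool, c("influx_factor", "tau_removal", "ca_rest"),
             "ca_pool")
  pool <- calcium_pool_spec(unlist(obj$ca_pool$influx_factor),
                            unlist(obj$ca_pool$tau_removal),
                            unlist(obj$ca_pool$ca_rest))
  neuron_config(comps, chans, pool, unlist(obj$conductance_table),
                frozen_parameters = unlist(obj$frozen_parameters))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment result to a directory
#'
#' Dispatches on the result class: population results become a samples CSV
#' plus a summary JSON, walk results a steps CSV, the bin-width-4 histogram
#' CSV and a summary JSON, data frames a plain CSV, traces the trace CSV.
#' Numeric JSON output keeps full precision.
#'
#' @param result a result object from this package.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir, prefix = "result") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  files <- character(0)
  if (inherits(result, "population_result")) {
    utils::write.csv(cbind(as.data.frame(result$samples), P = result$P,
                           valid = result$valid),
                     p("samples.csv"), row.names = FALSE)
    jsonlite::write_json(list(valid_fraction = result$valid_fraction,
                              ci_lo = unname(result$ci["lo"]),
                              ci_hi = unname(result$ci["hi"]),
                              n = length(result$P)),
                         p("summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(p("samples.csv"), p("summary.json"))
  } else if (inherits(result, "walk_result")) {
    utils::write.csv(data.frame(steps = result$steps), p("steps.csv"),
                     row.names = FALSE)
    utils::write.csv(result$histogram, p("histogram.csv"), row.names = FALSE)
    jsonlite::write_json(list(mean_steps = result$mean_steps,
                              n = length(result$steps)),
                         p("summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(p("steps.csv"), p("histogram.csv"), p("summary.json"))
  } else if (inherits(result, "voltage_trace")) {
    write_trace(result, p("trace.csv"))
    files <- p("trace.csv")
  } else if (inherits(result, "hyperplane_result")) {
    if (!is.null(result$grid)) {
      utils::write.csv(result$grid, p("hyperplane.csv"), row.names = FALSE)
      files <- p("hyperplane.csv")
    } else {
      jsonlite::write_json(list(weights = result$weights, P = result$P,
                                connected = result$connected),
                           p("hyperplane.json"), digits = NA)
      files <- p("hyperplane.json")
    }
  } else if (is.data.frame(result)) {
    utils::write.csv(result, p("table.csv"), row.names = FALSE)
    files <- p("table.csv")
  } else {
    jsonlite::write_json(result, p("result.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    files <- p("result.json")
  }
  invisible(files)
}

write_manifest <- function(dir, subcommand, seed, args, files, t0,
                           n_evaluations = NA) {
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    arguments = args,
    outputs = basename(files),
    package_version = as.character(utils::packageVersion("channelpop")),
    schema_version = SCHEMA_VERSION,
    n_evaluations = n_evaluations,
    wall_time_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Run one pipeline experiment end to end
#'
#' Seeded, manifest-writing dispatcher over the package's experiment
#' protocols. Subcommands: `simulate`, `features`, `fit`, `population`,
#' `sweep`, `walk`, `knockout`, `isoforms`, `hyperplane`, `toy`. Every
#' stochastic component receives a child seed derived from `seed`, so a run
#' is reproducible from its manifest.
#'
#' @param subcommand experiment name (see above).
#' @param out_dir output directory; receives the result files and exactly
#'   one `manifest.json`.
#' @param model baseline model id (`"gc5"`, `"gc9"`, `"gc15"`), where
#'   applicable.
#' @param seed global seed.
#' @param n samples (population/sweep/toy), @param reps walk repetitions.
#' @param amplitude stimulus amplitude (pA) for `simulate`/`features`.
#' @param range sweep half-widths, @param k_isoforms isoform count.
#' @param n_vars,rho,mode toy-model settings (`mode` one of
#'   `"independent"`, `"copula"`, `"distributed"`).
#' @param channel knockout channel name.
#' @param dt integrator step for model evaluations (ms).
#' @param max_steps walk cap.
#' @return The result object, invisibly; files are written to `out_dir`.
#' @export
run_experiment <- function(subcommand, out_dir, model = "gc5", seed = 1L,
                           n = 1000, reps = 200, amplitude = 90,
                           range = c(0.1, 0.2, 0.5), k_isoforms = 0,
                           n_vars = 5, rho = 0, mode = "independent",
                           channel = "BK", dt = 0.05, max_steps = 200) {
  t0 <- Sys.time()
  subcommand <- match.arg(subcommand,
    c("simulate", "features", "fit", "population", "sweep", "walk",
      "knockout", "isoforms", "hyperplane", "toy"))
  args <- list(model = model, n = n, reps = reps, amplitude = amplitude,
               range = range, k_isoforms = k_isoforms, n_vars = n_vars,
               rho = rho, mode = mode, channel = channel, dt = dt,
               max_steps = max_steps)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  solver <- solver_options(dt = dt)
  get_model <- function() make_baseline_models()[[model]]
  n_evals <- NA
  result <- switch(subcommand,
    simulate = {
      tr <- simulate_current_clamp(get_model(), stimulus_protocol(amplitude),
                                   solver, record_currents = TRUE)
      tr
    },
    features = {
      s <- model_session(get_model(), solver)
      trs <- session_simulate(s, c(50, 90), record_full = FALSE)
      fv <- extract_features(trs[[1]], trs[[2]])
      data.frame(feature = rep(names(fv$pA50), 2),
                 protocol = rep(c("pA50", "pA90"), each = 9),
                 value = c(unname(fv$pA50), unname(fv$pA90)))
    },
    fit = {
      cfg <- get_model()
      obj <- pareto_objective(cfg, solver = solver)
      start <- parameter_vector(cfg) *
        withr::with_seed(child_seed(seed, 1),
                         stats::runif(length(parameter_vector(cfg)), 0.5, 1.5))
      res <- conjugate_direction_search(obj, start,
                                        search_config(rng_seed = child_seed(seed, 2)))
      n_evals <- evaluation_count(obj)
      data.frame(parameter = names(res$best), value = unname(res$best),
                 best_P = res$best_P, termination = res$termination)
    },
    population = {
      cfg <- get_model()
      obj <- pareto_objective(cfg, solver = solver)
      s <- sample_population(cfg, n, seed = child_seed(seed, 1))
      r <- classify_population(s, obj)
      n_evals <- evaluation_count(obj)
      r
    },
    sweep = {
      cfg <- get_model()
      obj <- pareto_objective(cfg, solver = solver)
      r <- range_sweep(cfg, range, n_per = n, evaluator = obj,
                       seed = child_seed(seed, 1))
      n_evals <- evaluation_count(obj)
      r
    },
    walk = {
      cfg <- get_model()
      obj <- pareto_objective(cfg, solver = solver)
      r <- walk_ensemble(parameter_vector(cfg), obj, reps = reps,
                         max_steps = max_steps, seed = child_seed(seed, 1))
      n_evals <- evaluation_count(obj)
      r
    },
    knockout = {
      cfg <- get_model()
      r <- knockout_refit(cfg, channel, solver = solver,
                          search = search_config(rng_seed = child_seed(seed, 1)))
      data.frame(channel = channel, best_P = r$best_P, valid = r$best_P < 2,
                 termination = r$termination)
    },
    isoforms = {
      base5 <- make_baseline_models()$gc5
      r <- expand_isoforms(base5, k_isoforms, initial_sample_size = max(n, 3),
                           solver = solver, seed = child_seed(seed, 1))
      data.frame(k = r$k, P = r$P, valid = r$valid,
                 n_parameters = length(r$config$conductance_table))
    },
    hyperplane = {
      cfg <- get_model()
      obj <- pareto_objective(cfg, solver = solver)
      base <- parameter_vector(cfg)
      jitter <- withr::with_seed(child_seed(seed, 1),
        replicate(2, base * stats::runif(length(base), 0.95, 1.05),
                  simplify = FALSE))
      r <- hyperplane_pair(jitter[[1]], jitter[[2]], obj)
      n_evals <- evaluation_count(obj)
      r
    },
    toy = {
      m <- switch(mode,
        independent = sample_independent(n_vars, n, seed = child_seed(seed, 1)),
        copula = sample_copula(n_vars, rho, n, seed = child_seed(seed, 1)),
        distributed = sample_distributed(n_vars, n, seed = child_seed(seed, 1)),
        stop("unknown toy mode: ", mode))
      fr <- valid_fraction(m)
      ci <- wilson_ci(round(fr * n), n)
      data.frame(n_vars = n_vars, mode = mode, rho = rho, n_samples = n,
                 valid_fraction = fr, ci_lo = ci["lo"], ci_hi = ci["hi"],
                 row.names = NULL)
    })
  files <- write_results(result, out_dir, prefix = subcommand)
  write_manifest(out_dir, subcommand, seed, args, files, t0, n_evals)
  invisible(result)
}
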