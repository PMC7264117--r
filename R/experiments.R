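# Experiment orchestration: named, fully configured, reproducible experiment
# runs writing CSV/JSON bundles to disk. This is also the engine behind the
# command-line interface (inst/exec/gainfield).

# Registry of known configuration keys with their defaults, per experiment.
hardwired_defaults <- function() {
  list(
    retinal_range = c(-10, 10), eye_range = c(-35, 35), step = 1,
    sigma = 6, rho = 20, retinal_peak = 0.485, eye_peak = 0.485,
    phi_slope = 1.9, theta = 0.99
  )
}

selforg_defaults <- function() {
  list(
    retinal_range = c(-10, 10), eye_range = c(-35, 35), step = 1,
    sigma = 6, rho = 15, retinal_peak = 2, eye_peak = 2,
    phi_slope = 4.5, theta = 0,
    n_outputs = 100, connectivity = 10, learning_rate = 0.05,
    tau = 0.1, pi = 90,
    epochs = 10, fixation_duration = 0.3, saccade_speed = 400,
    schedule_mode = "fixation_defined", learn_during_saccades = TRUE
  )
}

experiment_registry <- function() {
  list(
    hardwired_curves = list(
      defaults = c(hardwired_defaults(),
                   list(neurons = "(-10,-34);(-5,-18);(0,0);(5,18);(10,34)")),
      run = exp_hardwired_curves),
    hardwired_rho_sweep = list(
      defaults = c(hardwired_defaults(),
                   list(rho_values = c(2.5, 5, 10, 15, 20, 25))),
      run = exp_hardwired_rho_sweep),
    hardwired_multiplicativity = list(
      defaults = c(hardwired_defaults(),
                   list(rho = 15,
                        neurons = "(-10,-34);(-10,-25);(10,34)",
                        fixations = c(-35, -12, 0, 12, 35),
                        tolerance = 0.05)),
      run = exp_hardwired_multiplicativity),
    selforg_train = list(
      defaults = selforg_defaults(),
      run = exp_selforg_train),
    selforg_rho_sweep = list(
      defaults = c(selforg_defaults(), list(rho_values = c(2.5, 5, 10, 15, 20, 25))),
      run = exp_selforg_rho_sweep),
    selforg_multiplicativity = list(
      defaults = utils::modifyList(
        selforg_defaults(),
        list(rho = 17, fixations = c(-20, -12, 0, 12, 20), tolerance = 0.05)),
      run = exp_selforg_multiplicativity)
  )
}

#' Build and validate an experiment configuration
#'
#' Resolves an experiment's configuration from its defaults overridden by
#' `overrides` (and, at the command line, by flags). Unknown keys are
#' rejected with the offending key named.
#'
#' @param experiment Experiment name; one of `hardwired_curves`,
#'   `hardwired_rho_sweep`, `hardwired_multiplicativity`, `selforg_train`,
#'   `selforg_rho_sweep`, `selforg_multiplicativity`.
#' @param overrides Named list of configuration values to override.
#' @param seed Integer master seed.
#'
#' @return An object of class `"experiment_config"`: the resolved
#'   configuration with `experiment` and `seed` fields.
#' @export
#' @examples
#' cfg <- experiment_config("hardwired_rho_sweep", list(rho_values = c(2.5, 25)))
#' cfg$rho_values
experiment_config <- function(experiment, overrides = list(), seed = 1) {
  reg <- experiment_registry()
  if (!experiment %in% names(reg)) {
    stop(sprintf("unknown experiment '%s' (known: %s)", experiment,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  defaults <- reg[[experiment]]$defaults
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s) for %s: %s", experiment,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$experiment <- experiment
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "experiment_config")
}

#' Read a configuration file
#'
#' Reads a flat YAML configuration file. The file may contain an `experiment`
#' and `seed` key plus any keys valid for that experiment; `overrides` (e.g.
#' command-line flags) take precedence over file values, which take
#' precedence over defaults.
#'
#' @param path Path to a YAML file.
#' @param experiment Experiment name; defaults to the file's `experiment` key.
#' @param overrides Named list overriding file values.
#' @param seed Seed; overrides the file's `seed` key when non-`NULL`.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, experiment = NULL, overrides = list(),
                                   seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (is.null(experiment)) experiment <- vals$experiment
  if (is.null(experiment)) stop("no `experiment` key in file and none supplied", call. = FALSE)
  if (is.null(seed)) seed <- if (!is.null(vals$seed)) vals$seed else 1
  vals$experiment <- NULL
  vals$seed <- NULL
  vals <- utils::modifyList(vals, overrides)
  experiment_config(experiment, vals, seed = seed)
}

#' Write a configuration file
#'
#' @param config An [experiment_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Polynomial rolling hash over the canonical JSON serialization: a short
# provenance fingerprint embedded in every result bundle.
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(js)
  hash <- 17
  for (b in bytes) hash <- (hash * 31 + b) %% 2147483647
  sprintf("%08x", hash)
}

# One master seed expands into named independent sub-seeds (connectivity and
# weights, training schedule, ...) so changing one consumer does not perturb
# the others.
derive_seeds <- function(seed, names) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

parse_neuron_list <- function(spec) {
  # "(-10,-34);(-5,-18)" -> data.frame(alpha, beta)
  parts <- strsplit(gsub("[() ]", "", spec), ";")[[1]]
  pairs <- do.call(rbind, lapply(strsplit(parts, ","), as.numeric))
  data.frame(alpha = pairs[, 1], beta = pairs[, 2])
}

grid_from_config <- function(cfg) {
  build_population(
    retinal_range = cfg$retinal_range, eye_range = cfg$eye_range,
    step = cfg$step, retinal_width = cfg$sigma, eye_width = cfg$rho,
    retinal_peak = cfg$retinal_peak, eye_peak = cfg$eye_peak,
    sigmoid = sigmoid_spec(cfg$phi_slope, cfg$theta))
}

layer_from_config <- function(cfg) {
  input_layer(eye_range = cfg$eye_range, retinal_range = cfg$retinal_range,
              step = cfg$step, eye_width = cfg$rho, retinal_width = cfg$sigma,
              eye_peak = cfg$eye_peak, retinal_peak = cfg$retinal_peak,
              sigmoid = sigmoid_spec(cfg$phi_slope, cfg$theta))
}

train_from_config <- function(cfg, rho = NULL, seed_offset = 0L) {
  cfg2 <- cfg
  if (!is.null(rho)) cfg2$rho <- rho
  layer <- layer_from_config(cfg2)
  seeds <- derive_seeds(cfg$seed + seed_offset, c("network", "schedule"))
  net <- init_network(seeds[["network"]], layer, n_outputs = cfg$n_outputs,
                      connectivity = cfg$connectivity,
                      learning_rate = cfg$learning_rate, tau = cfg$tau,
                      sparseness = cfg$pi,
                      sigmoid = sigmoid_spec(cfg$phi_slope, cfg$theta))
  sched <- make_schedule(seeds[["schedule"]], epochs = cfg$epochs,
                         retinal_locations = seq(cfg$retinal_range[1],
                                                 cfg$retinal_range[2],
                                                 by = cfg$step),
                         fixation_duration = cfg$fixation_duration,
                         saccade_speed = cfg$saccade_speed,
                         eye_range = cfg$eye_range,
                         schedule_mode = cfg$schedule_mode)
  fit <- run_training(net, layer, sched,
                      learn_during_saccades = cfg$learn_during_saccades)
  list(layer = layer, network = fit$network, log = fit$log)
}

write_provenance <- function(cfg, output_dir, extra = list()) {
  info <- c(list(experiment = cfg$experiment, seed = cfg$seed,
                 config_hash = config_hash(cfg)),
            extra)
  jsonlite::write_json(info, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

exp_hardwired_curves <- function(cfg, output_dir) {
  grid <- grid_from_config(cfg)
  neurons <- parse_neuron_list(cfg$neurons)
  curves <- list(); stats <- list()
  for (i in seq_len(nrow(neurons))) {
    n <- hardwired_neuron(neurons$alpha[i], neurons$beta[i])
    cv <- eye_sweep(n, grid)
    lr <- linearity_r2(cv)
    curves[[i]] <- data.frame(alpha = n$alpha, beta = n$beta,
                              eye_y = cv$abscissa, rate = cv$rates)
    stats[[i]] <- data.frame(alpha = n$alpha, beta = n$beta,
                             r_squared = lr$r_squared, slope = lr$slope,
                             intercept = lr$intercept)
  }
  utils::write.csv(do.call(rbind, curves), file.path(output_dir, "curves.csv"),
                   row.names = FALSE)
  r2 <- do.call(rbind, stats)
  utils::write.csv(r2, file.path(output_dir, "r_squared.csv"), row.names = FALSE)
  list(r_squared = r2)
}

exp_hardwired_rho_sweep <- function(cfg, output_dir) {
  out <- list()
  for (rho in cfg$rho_values) {
    cfg2 <- cfg; cfg2$rho <- rho
    grid <- grid_from_config(cfg2)
    lin <- population_linearity(grid)
    hist <- r2_histogram(lin$r_squared)
    df <- as.data.frame(hist)
    utils::write.csv(df, file.path(output_dir, sprintf("histogram_rho_%g.csv", rho)),
                     row.names = FALSE)
    out[[as.character(rho)]] <- list(
      rho = rho, n = hist$n,
      percent_per_bin = hist$proportions,
      percent_r2_le_0.2 = 100 * mean(lin$r_squared <= 0.2),
      median_r2 = stats::median(lin$r_squared))
  }
  list(rho_sweep = out)
}

exp_hardwired_multiplicativity <- function(cfg, output_dir) {
  grid <- grid_from_config(cfg)
  neurons <- parse_neuron_list(cfg$neurons)
  rows <- list()
  for (i in seq_len(nrow(neurons))) {
    n <- hardwired_neuron(neurons$alpha[i], neurons$beta[i])
    fam <- retinal_sweep_family(n, grid, cfg$fixations)
    mt <- multiplicativity_test(fam, tolerance = cfg$tolerance)
    rows[[i]] <- data.frame(alpha = n$alpha, beta = n$beta,
                            fixation = mt$fixations,
                            scale_constant = mt$scale_constants,
                            relative_residual = mt$relative_residuals,
                            passes = mt$passes)
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(output_dir, "multiplicativity.csv"),
                   row.names = FALSE)
  list(max_relative_residual = max(df$relative_residual),
       all_pass = all(df$passes))
}

exp_selforg_train <- function(cfg, output_dir) {
  fit <- train_from_config(cfg)
  save_network(fit$network, file.path(output_dir, "checkpoint"))
  utils::write.csv(fit$log, file.path(output_dir, "training_log.csv"),
                   row.names = FALSE)
  lin <- trained_population_linearity(fit$network, fit$layer)
  utils::write.csv(lin, file.path(output_dir, "output_linearity.csv"),
                   row.names = FALSE)
  r2 <- lin$r_squared[lin$active]
  list(n_active = sum(lin$active),
       r2_range = if (length(r2)) c(min(r2), max(r2)) else NULL,
       mean_sparseness = mean(fit$log$mean_sparseness),
       profiles = as.list(table(lin$profile)))
}

exp_selforg_rho_sweep <- function(cfg, output_dir) {
  out <- list()
  for (rho in cfg$rho_values) {
    fit <- train_from_config(cfg, rho = rho)
    lin <- trained_population_linearity(fit$network, fit$layer)
    utils::write.csv(lin, file.path(output_dir,
                                    sprintf("output_linearity_rho_%g.csv", rho)),
                     row.names = FALSE)
    out[[as.character(rho)]] <- list(
      rho = rho,
      profiles = as.list(table(lin$profile)),
      median_active_r2 = stats::median(lin$r_squared[lin$active]))
  }
  list(rho_sweep = out)
}

exp_selforg_multiplicativity <- function(cfg, output_dir) {
  fit <- train_from_config(cfg)
  lin <- trained_population_linearity(fit$network, fit$layer)
  mono <- lin$unit[lin$profile == "monotonic" & lin$active]
  rows <- list()
  for (u in mono) {
    fam <- output_retinal_family(fit$network, fit$layer, u, cfg$fixations)
    mt <- multiplicativity_test(fam, tolerance = cfg$tolerance)
    rows[[length(rows) + 1L]] <- data.frame(
      unit = u, max_relative_residual = mt$max_relative_residual,
      passes = mt$passes)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = integer(), max_relative_residual = numeric(),
               passes = logical())
  utils::write.csv(df, file.path(output_dir, "multiplicativity.csv"),
                   row.names = FALSE)
  list(n_monotonic = length(mono),
       n_passing = sum(df$passes),
       median_residual = if (nrow(df)) stats::median(df$max_relative_residual) else NULL)
}

#' Run a named experiment
#'
#' Executes one of the registered experiments with a resolved configuration,
#' writing CSV results, a frozen copy of the configuration and a JSON summary
#' (with seed and configuration hash for provenance) to `output_dir`.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config An [experiment_config()], or an experiment name (then
#'   `overrides`/`seed` apply).
#' @param output_dir Directory for the result bundle (created if needed).
#' @param overrides,seed Used when `config` is an experiment name.
#'
#' @return The summary list, invisibly.
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' run_experiment("hardwired_curves", dir)
#' read.csv(file.path(dir, "r_squared.csv"))
#' }
run_experiment <- function(config, output_dir, overrides = list(), seed = 1) {
  if (is.character(config)) {
    config <- experiment_config(config, overrides, seed = seed)
  }
  if (!inherits(config, "experiment_config")) {
    stop("`config` must be an experiment_config or experiment name", call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- experiment_registry()
  summary <- reg[[config$experiment]]$run(config, output_dir)
  write_provenance(config, output_dir, summary)
  invisible(summary)
}
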