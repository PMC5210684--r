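# Run configuration: a JSON schema shared by the library and the CLI.
# Keys: n_stages, mean_cycle_time_h or lambdas, strategy {name, k, params}
# or explicit ks, burst {kind, mean | pmf}, alpha, degradation_rate, seed.

CONFIG_SCHEMA_VERSION <- "1"

config_allowed_keys <- c("n_stages", "mean_cycle_time_h", "lambdas",
                         "strategy", "ks", "burst", "alpha",
                         "degradation_rate", "seed", "schema_version")

#' Parse a model configuration
#'
#' Reads a JSON file (or takes an equivalent named list) describing a model
#' and returns a validated run configuration with defaults resolved: equal
#' stage rates from `mean_cycle_time_h`, `geometric1` bursts, binomial
#' partitioning (`alpha = 1`) and `seed = 0`. Unknown keys are rejected so
#' that typos fail loudly.
#'
#' @param config Path to a JSON file, or a named list with the same keys.
#' @return An object of class `"run_config"`: list with `model` (a
#'   [model_spec()]), `seed`, and the fully resolved `resolved` list that is
#'   embedded in every output artifact for reproducibility.
#' @examples
#' cfg <- parse_config(list(n_stages = 20, mean_cycle_time_h = 2,
#'                          strategy = list(name = "constant", k = 1),
#'                          burst = list(kind = "geometric1", mean = 4),
#'                          alpha = 1))
#' @export
parse_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a file path or a named list")
  unknown <- setdiff(names(config), config_allowed_keys)
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff("n_stages", names(config))
  if (is.null(config$n_stages)) {
    stopf("config must define: n_stages (plus mean_cycle_time_h or lambdas, and strategy or ks)")
  }
  if (is.null(config$mean_cycle_time_h) && is.null(config$lambdas)) {
    stopf("config must define 'mean_cycle_time_h' or 'lambdas'")
  }
  cycle <- make_cell_cycle(config$n_stages,
                           mean_T = config$mean_cycle_time_h,
                           lambdas = config$lambdas)
  if (!is.null(config$ks)) {
    ks <- as.numeric(config$ks)
    strategy <- NULL
  } else if (!is.null(config$strategy)) {
    s <- config$strategy
    if (is.null(s$name) || is.null(s$k)) {
      stopf("config key 'strategy' needs fields 'name' and 'k'")
    }
    ks <- make_strategy(s$name, k = s$k, cycle = cycle,
                        params = if (is.null(s$params)) list() else as.list(s$params))
    strategy <- s
  } else {
    stopf("config must define 'strategy' {name, k} or explicit 'ks'")
  }
  b <- config$burst
  if (is.null(b)) b <- list(kind = "geometric1", mean = 4)
  if (is.null(b$kind)) b$kind <- "geometric1"
  burst <- burst_model(b$kind, mean = b$mean, pmf = b$pmf)
  alpha <- if (is.null(config$alpha)) 1 else config$alpha
  degr <- if (is.null(config$degradation_rate)) 0 else config$degradation_rate
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  model <- model_spec(cycle, ks, burst, partition_model(alpha), degr)
  resolved <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    n_stages = cycle$n,
    lambdas = cycle$lambdas,
    mean_cycle_time_h = cycle$mean_T,
    ks = model$regulation,
    strategy = strategy,
    burst = list(kind = burst$kind, mean = burst$mean,
                 second_moment = burst$second_moment),
    alpha = alpha,
    degradation_rate = degr,
    seed = seed
  )
  structure(list(model = model, seed = seed, resolved = resolved),
            class = "run_config")
}

#' Serialize a run configuration back to its JSON form
#'
#' The resolved configuration round-trips: `parse_config(config_as_list(x))`
#' reproduces an equivalent `run_config`.
#'
#' @param rc A [parse_config()] result.
#' @return A named list using the config schema keys.
#' @export
config_as_list <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  r <- rc$resolved
  list(n_stages = r$n_stages, lambdas = r$lambdas, ks = r$ks,
       burst = list(kind = r$burst$kind, mean = r$burst$mean),
       alpha = r$alpha, degradation_rate = r$degradation_rate,
       seed = r$seed, schema_version = r$schema_version)
}

fmt12 <- function(x) signif(x, 12)

#' Write a noise or simulation summary as JSON
#'
#' Stable key order, floats at 12 significant digits, and the seed plus the
#' fully resolved configuration embedded for reproducibility.
#'
#' @param summary A `"noise_summary"`, `"sim_summary"`, `"moment_state"` or
#'   plain named list.
#' @param path Output file path.
#' @param config Optional [parse_config()] object to embed.
#' @param seed Optional seed to record (defaults to the config's).
#' @return The path, invisibly.
#' @export
write_summary_json <- function(summary, path, config = NULL, seed = NULL) {
  payload <- if (inherits(summary, "moment_state")) {
    list(values = as.list(fmt12(summary$values)),
         mean_x = fmt12(summary$mean_x), var_z = fmt12(summary$var_z),
         eta = fmt12(summary$eta))
  } else {
    lapply(unclass(summary), function(v) if (is.numeric(v)) fmt12(v) else v)
  }
  if (!is.null(config)) {
    payload$config <- config$resolved
    if (is.null(seed)) seed <- config$seed
  }
  if (!is.null(seed)) payload$seed <- seed
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a lineage trajectory as TSV
#'
#' Fixed column order `time_h, generation, stage, x, y, z, event`, header
#' row, floats at 12 significant digits; parseable back into an equal record
#' sequence with [read_trajectory_tsv()].
#'
#' @param traj A [simulate_lineage()] trajectory.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "lineage_trajectory"))
  out <- data.frame(time_h = fmt12(traj$time), generation = traj$generation,
                    stage = traj$stage, x = traj$x, y = fmt12(traj$y),
                    z = fmt12(traj$z), event = traj$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory_tsv()]
#'
#' @param path File path.
#' @return A data frame with columns `time_h`, `generation`, `stage`, `x`,
#'   `y`, `z`, `event`.
#' @export
read_trajectory_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a strategy comparison (or any table) as CSV
#'
#' @param table A data frame, e.g. from [compare_strategies()] or
#'   [duplication_scan()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_comparison_csv <- function(table, path) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], fmt12)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
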