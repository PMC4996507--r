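#' Load a run configuration from a YAML or JSON file
#'
#' The file names a published scenario (`scenario: 1..7`, optionally
#' `robustness: true`) or supplies a custom agent table (`agents:` with
#' fields `informed`, `confidence`, `social_skills`, `social_preferences`),
#' plus optional overrides: `n_ticks`, `initial_stock`, `replications`,
#' `base_seed`, `trust_range`, `informed_range`, `uninformed_range`, a
#' `params` block with [behavior_params()] fields, and `regen_table` (a path
#' to a regeneration-table CSV, resolved relative to the configuration
#' file). Unknown keys produce a warning; invariant violations are collected
#' and reported together.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `config` (a [scenario_config()]), `params`
#'   (a [behavior_params()]) and `table` (a [regen_table()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()

  known <- c("scenario", "robustness", "agents", "n_ticks", "initial_stock",
             "replications", "base_seed", "trust_range", "informed_range",
             "uninformed_range", "params", "regen_table", "scenario_id")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }

  params <- do.call(behavior_params, as.list(raw$params))

  table <- if (!is.null(raw$regen_table)) {
    tab_path <- raw$regen_table
    if (!file.exists(tab_path)) {
      tab_path <- file.path(dirname(path), raw$regen_table)
    }
    read_regen_table(tab_path)
  } else {
    default_regen_table()
  }

  overrides <- raw[intersect(names(raw), c(
    "n_ticks", "initial_stock", "replications", "base_seed",
    "trust_range", "informed_range", "uninformed_range", "scenario_id"
  ))]
  if (isTRUE(raw$robustness) && is.null(raw$trust_range)) {
    overrides$trust_range <- c(0.66, 0.80)
  }

  config <- if (!is.null(raw[["scenario"]])) {
    do.call(scenario, c(list(id = raw[["scenario"]],
                             robustness = isTRUE(raw$robustness)),
                        overrides))
  } else if (!is.null(raw$agents)) {
    do.call(scenario_config,
            c(list(agents = as.data.frame(raw$agents)), overrides))
  } else {
    stop("configuration must name a scenario (1-7) or supply an agents table",
         call. = FALSE)
  }
  list(config = config, params = params, table = table)
}

#' Load sweep factor levels from a YAML or JSON file
#'
#' The file may override any factor of [default_sweep_levels()]; omitted
#' factors keep their default levels.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of factor levels.
#' @export
load_sweep_levels <- function(path) {
  if (!file.exists(path)) stop("sweep file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  levels <- default_sweep_levels()
  for (nm in names(raw)) {
    if (!nm %in% names(levels)) {
      warning("ignoring unknown sweep factor: ", nm, call. = FALSE)
    } else {
      levels[[nm]] <- raw[[nm]]
    }
  }
  levels
}

# Canonical serialization of a configuration (for hashing and round trips).
.config_as_list <- function(config, params) {
  list(
    scenario_id = config$scenario_id,
    agents = lapply(config$agents, function(col) unname(col)),
    n_ticks = config$n_ticks,
    initial_stock = config$initial_stock,
    informed_range = config$informed_range,
    uninformed_range = config$uninformed_range,
    trust_range = config$trust_range,
    replications = config$replications,
    base_seed = config$base_seed,
    params = unclass(params)
  )
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization of the scenario configuration and
#' behavioral parameters; equivalent configurations hash identically.
#'
#' @param config A [scenario_config()] object.
#' @param params A [behavior_params()] object.
#' @return A hex string.
#' @export
config_hash <- function(config, params = behavior_params()) {
  json <- jsonlite::toJSON(.config_as_list(config, params),
                           auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a configuration to YAML
#'
#' The written file reloads with [load_config()] to an equivalent
#' configuration (identical [config_hash()]).
#'
#' @param config A [scenario_config()] object.
#' @param params A [behavior_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, params, path) {
  x <- .config_as_list(config, params)
  x$agents <- as.data.frame(x$agents)
  yaml::write_yaml(x, path)
  invisible(path)
}

# Fixed-precision numeric formatting for diffable CSV output.
.round_numerics <- function(df, digits = 9) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], digits)
  }
  df
}

#' Write batch outputs to a directory
#'
#' Writes `trajectories.csv` (long format: one row per run, tick and agent,
#' with the tick-level stock and agreement columns repeated), `summary.csv`
#' (per-tick mean reported stock), `classification.csv` (one row per run) and
#' `manifest.json`. Requires a batch run with `keep_runs = TRUE`.
#'
#' @param batch A `cpr_batch` from [simulate_batch()].
#' @param dir Output directory (created if needed).
#' @param params The [behavior_params()] the batch was run with (recorded in
#'   the manifest hash).
#' @return Invisibly, the manifest as a list.
#' @export
write_batch_outputs <- function(batch, dir, params = behavior_params()) {
  if (is.null(batch$runs)) {
    stop("batch was run without keep_runs = TRUE; no trajectories to write",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  traj <- do.call(rbind, lapply(batch$runs, function(r) {
    df <- merge(r$agents, r$ticks, by = "tick", sort = FALSE)
    df$run <- r$seed - batch$config$base_seed
    df$seed <- r$seed
    df
  }))
  lead <- c("run", "seed", "tick", "agent_id")
  traj <- traj[order(traj$run, traj$tick, traj$agent_id),
               c(lead, setdiff(names(traj), lead))]
  utils::write.csv(.round_numerics(traj),
                   file.path(dir, "trajectories.csv"), row.names = FALSE)

  summary_df <- data.frame(
    tick = seq_along(batch$mean_stock),
    mean_stock_reported = batch$mean_stock
  )
  utils::write.csv(.round_numerics(summary_df),
                   file.path(dir, "summary.csv"), row.names = FALSE)

  cls <- batch$run_stats
  cls$config_id <- batch$config$scenario_id
  utils::write.csv(.round_numerics(cls),
                   file.path(dir, "classification.csv"), row.names = FALSE)

  write_manifest(dir, batch$config, params,
                 files = c("trajectories.csv", "summary.csv",
                           "classification.csv"))
}

#' Write a run manifest
#'
#' @param dir Output directory.
#' @param config A [scenario_config()] object.
#' @param params A [behavior_params()] object.
#' @param files Output files recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_manifest <- function(dir, config, params = behavior_params(),
                           files = character(0)) {
  manifest <- list(
    artifact = "cprsim",
    version = as.character(utils::packageVersion("cprsim")),
    scenario_id = config$scenario_id,
    config_hash = config_hash(config, params),
    base_seed = config$base_seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a trajectories CSV back into runs
#'
#' Reconstructs minimal `cpr_run` objects (tick- and agent-level tables) from
#' a long-format `trajectories.csv`, sufficient for the classification
#' functions.
#'
#' @param path Path to `trajectories.csv`.
#' @return A list of `cpr_run` objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  tick_cols <- c("tick", "stock_start", "group_knowledge", "group_total",
                 "group_share", "total_extraction", "post_harvest",
                 "stock_reported")
  lapply(split(df, df$run), function(d) {
    d <- d[order(d$tick, d$agent_id), ]
    ticks <- unique(d[, intersect(tick_cols, names(d))])
    agents <- d[, setdiff(names(d), setdiff(tick_cols, "tick"))]
    structure(list(config = NULL, seed = d$seed[1], ticks = ticks,
                   agents = agents),
              class = "cpr_run")
  })
}
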