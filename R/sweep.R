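#' Factor levels of the default factorial sweep
#'
#' The default exploration grid crosses group-composition factors over a
#' four-agent group template:
#'
#' * `knowledge_profile`: `all_low` (four uninformed agents, knowledge
#'   10-24), `all_msy` (four informed agents, knowledge 25-29), `all_high`
#'   (four cautious agents, knowledge 32-45), `one_msy_rest_low` and
#'   `two_msy_rest_low` (mixed groups).
#' * `confidence_profile`: `all_low` (0.2), `all_high` (0.8), `first_high`
#'   (0.8 for agent 1, 0.2 for the rest).
#' * `skills_profile`: `all_speak` (social skills 1), `half` (0.5),
#'   `one_speaker` (agent 1 speaks, the rest never).
#' * `trust_level`: `low` (0.05-0.35), `mid` (0.35-0.65), `high`
#'   (0.66-0.94).
#' * `social_preferences`: all agents `TRUE` or all `FALSE`.
#'
#' The full cross yields 270 configurations spanning homogeneous and
#' heterogeneous groups, which suffices to reproduce the qualitative outcome
#' patterns (see [pattern_check()]).
#'
#' @return A named list of factor levels, as consumed by [sweep_grid()].
#' @export
default_sweep_levels <- function() {
  list(
    knowledge_profile = c("all_low", "all_msy", "all_high",
                          "one_msy_rest_low", "two_msy_rest_low"),
    confidence_profile = c("all_low", "all_high", "first_high"),
    skills_profile = c("all_speak", "half", "one_speaker"),
    trust_level = c("low", "mid", "high"),
    social_preferences = c(TRUE, FALSE)
  )
}

#' Expand factor levels into a sweep grid
#'
#' @param levels Named list of factor levels; see [default_sweep_levels()]
#'   for the recognized factors and values.
#' @return A data frame with one row per configuration and a `config_id`
#'   column.
#' @export
sweep_grid <- function(levels = default_sweep_levels()) {
  required <- names(default_sweep_levels())
  missing <- setdiff(required, names(levels))
  if (length(missing)) {
    stop("sweep specification is missing factor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(levels[required]) == 0)) {
    stop("every sweep factor needs at least one level", call. = FALSE)
  }
  grid <- expand.grid(levels[required], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$config_id <- seq_len(nrow(grid))
  grid[, c("config_id", required)]
}

.trust_range_for <- function(level) {
  switch(level,
    low = c(0.05, 0.35),
    mid = c(0.35, 0.65),
    high = c(0.66, 0.94),
    stop("unknown trust level: ", level, call. = FALSE)
  )
}

# Build a scenario_config for one sweep grid row.
.sweep_config <- function(row, n_ticks = 14, replications = 100,
                          base_seed = 1L) {
  informed <- switch(row$knowledge_profile,
    all_low = rep(FALSE, 4),
    all_msy = rep(TRUE, 4),
    all_high = rep(FALSE, 4),
    one_msy_rest_low = c(TRUE, FALSE, FALSE, FALSE),
    two_msy_rest_low = c(TRUE, TRUE, FALSE, FALSE),
    stop("unknown knowledge profile: ", row$knowledge_profile, call. = FALSE)
  )
  uninformed_range <- if (row$knowledge_profile == "all_high") c(32, 45) else c(10, 24)
  confidence <- switch(row$confidence_profile,
    all_low = rep(0.2, 4),
    all_high = rep(0.8, 4),
    first_high = c(0.8, 0.2, 0.2, 0.2),
    stop("unknown confidence profile: ", row$confidence_profile, call. = FALSE)
  )
  skills <- switch(row$skills_profile,
    all_speak = rep(1, 4),
    half = rep(0.5, 4),
    one_speaker = c(1, 0, 0, 0),
    stop("unknown skills profile: ", row$skills_profile, call. = FALSE)
  )
  scenario_config(
    data.frame(informed = informed, confidence = confidence,
               social_skills = skills,
               social_preferences = rep(row$social_preferences, 4)),
    scenario_id = sprintf("sweep-%d", row$config_id),
    uninformed_range = uninformed_range,
    trust_range = .trust_range_for(row$trust_level),
    n_ticks = n_ticks,
    replications = replications,
    base_seed = base_seed
  )
}

#' Run a factorial sweep over group compositions
#'
#' Runs a replicated batch for every configuration of the grid and stacks the
#' run-level classifications into one long table, the validation surface for
#' the pattern-oriented checks.
#'
#' @param grid A grid from [sweep_grid()].
#' @param replications Replicate runs per configuration.
#' @param n_ticks Ticks per run.
#' @param table A [regen_table()] object.
#' @param params A [behavior_params()] object.
#' @param base_seed Base seed. Configuration `i` uses base seeds offset by
#'   `i * seed_stride` so replicate seeds never collide across
#'   configurations.
#' @param seed_stride Seed offset between configurations.
#' @param progress Print a progress line every 25 configurations.
#' @return An object of class `cpr_sweep`: list with the `grid`, a combined
#'   run-level data frame `run_stats` (with `config_id`), a per-configuration
#'   summary data frame `config_stats`, and the [pattern_check()] report
#'   `patterns`.
#' @export
run_sweep <- function(grid = sweep_grid(), replications = 100, n_ticks = 14,
                      table = default_regen_table(),
                      params = behavior_params(), base_seed = 1L,
                      seed_stride = 10000L, progress = FALSE) {
  if (nrow(grid) == 0) stop("empty sweep grid", call. = FALSE)
  stats_list <- vector("list", nrow(grid))
  config_stats <- grid
  config_stats$cooperative_fraction <- NA_real_
  config_stats$config_cooperative <- NA
  config_stats$over <- NA_real_
  config_stats$optimal <- NA_real_
  config_stats$under <- NA_real_
  config_stats$mean_final_stock <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- .sweep_config(grid[i, ], n_ticks = n_ticks,
                         replications = replications,
                         base_seed = base_seed + (i - 1L) * seed_stride)
    b <- simulate_batch(cfg, table, params)
    rs <- b$run_stats
    rs$config_id <- grid$config_id[i]
    stats_list[[i]] <- rs
    config_stats$cooperative_fraction[i] <- b$cooperative_fraction
    config_stats$config_cooperative[i] <- b$config_cooperative
    config_stats$over[i] <- b$exploitation_freq[["over"]]
    config_stats$optimal[i] <- b$exploitation_freq[["optimal"]]
    config_stats$under[i] <- b$exploitation_freq[["under"]]
    config_stats$mean_final_stock[i] <- b$mean_stock[n_ticks]
    if (progress && i %% 25 == 0) {
      message(sprintf("sweep: %d/%d configurations done", i, nrow(grid)))
    }
  }
  run_stats <- do.call(rbind, stats_list)
  structure(
    list(grid = grid, run_stats = run_stats, config_stats = config_stats,
         patterns = pattern_check(run_stats)),
    class = "cpr_sweep"
  )
}

#' @export
print.cpr_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %d configurations, %d runs total\n",
              nrow(x$grid), nrow(x$run_stats)))
  p <- x$patterns
  cat(sprintf("  patterns: a (coop & non-coop) %s; b (all classes) %s; c (all classes in coop) %s\n",
              p$a, p$b, p$c))
  cat(sprintf("  cooperative configurations: %d\n",
              sum(x$config_stats$config_cooperative)))
  invisible(x)
}
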