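#' Scenario configuration for a simulated harvesting group
#'
#' Describes how a group of agents is initialized and how the game is run:
#' per-agent traits (informed or not, confidence, social skills, social
#' preferences), the ranges from which initial knowledge and trust are drawn,
#' the number of ticks, the starting stock, and the replication settings.
#'
#' Initial knowledge is drawn uniformly over the integers of the agent's
#' range: `informed_range` for informed agents (the MSY stock bin by
#' default) and `uninformed_range` otherwise. Initial trust is drawn
#' uniformly (real-valued) from `trust_range`.
#'
#' @param agents A data frame with one row per agent and columns `informed`
#'   (logical), `confidence` (initial value in `[0, 1]`), `social_skills`
#'   (speaking probability in `[0, 1]`) and `social_preferences` (logical).
#' @param scenario_id Label for the configuration.
#' @param n_ticks Number of ticks per run.
#' @param initial_stock Starting stock size.
#' @param informed_range Integer knowledge range for informed agents.
#' @param uninformed_range Integer knowledge range for uninformed agents.
#' @param trust_range Range of the uniform initial trust draw.
#' @param replications Number of replicate runs in a batch.
#' @param base_seed Base seed; run `i` of a batch uses `base_seed + i`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(agents,
                            scenario_id = "custom",
                            n_ticks = 14,
                            initial_stock = 50,
                            informed_range = c(25, 29),
                            uninformed_range = c(10, 24),
                            trust_range = c(0.66, 0.94),
                            replications = 5000,
                            base_seed = 1L) {
  agents <- as.data.frame(agents)
  required <- c("informed", "confidence", "social_skills", "social_preferences")
  problems <- character(0)
  missing_cols <- setdiff(required, names(agents))
  if (length(missing_cols)) {
    problems <- c(problems, sprintf("agents is missing column(s): %s",
                                    paste(missing_cols, collapse = ", ")))
  } else {
    if (nrow(agents) < 1) problems <- c(problems, "need at least one agent")
    if (any(agents$confidence < 0 | agents$confidence > 1)) {
      problems <- c(problems, "agent confidence must be in [0, 1]")
    }
    if (any(agents$social_skills < 0 | agents$social_skills > 1)) {
      problems <- c(problems, "agent social_skills must be in [0, 1]")
    }
  }
  check_range <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      sprintf("%s must be an increasing pair within [%g, %g]", nm, lo, hi)
    }
  }
  problems <- c(
    problems,
    check_range(informed_range, "informed_range", 5, 50),
    check_range(uninformed_range, "uninformed_range", 5, 50),
    check_range(trust_range, "trust_range", 0, 1),
    if (n_ticks < 1) "n_ticks must be >= 1",
    if (initial_stock < 0) "initial_stock must be >= 0",
    if (replications < 1) "replications must be >= 1"
  )
  if (length(problems)) {
    stop("invalid scenario configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(
    list(
      scenario_id = as.character(scenario_id),
      agents = agents,
      n_agents = nrow(agents),
      n_ticks = as.integer(n_ticks),
      initial_stock = as.numeric(initial_stock),
      informed_range = as.numeric(informed_range),
      uninformed_range = as.numeric(uninformed_range),
      trust_range = as.numeric(trust_range),
      replications = as.integer(replications),
      base_seed = as.integer(base_seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d agents, %d ticks from stock %g, %d replications\n",
              x$scenario_id, x$n_agents, x$n_ticks, x$initial_stock,
              x$replications))
  cat(sprintf("  informed knowledge %g-%g, uninformed %g-%g, trust [%g, %g]\n",
              x$informed_range[1], x$informed_range[2],
              x$uninformed_range[1], x$uninformed_range[2],
              x$trust_range[1], x$trust_range[2]))
  print(x$agents)
  invisible(x)
}

#' The seven published group compositions
#'
#' Scenario set I (1-3) varies the number of informed, highly confident
#' agents in a group where everyone speaks; set II (4-7) fixes one informed
#' and three uninformed agents and varies who speaks and how confident the
#' speakers are. In every scenario all agents have social preferences, at
#' least one agent speaks, non-speakers are uninformed with low confidence,
#' and initial trust is high (drawn from 0.66-0.94, or 0.66-0.80 under the
#' increased social-uncertainty robustness variant).
#'
#' * S1: four uninformed, low-confidence speakers.
#' * S2: as S1 with one agent replaced by an informed, high-confidence speaker.
#' * S3: two informed high-confidence speakers, two uninformed low-confidence
#'   speakers.
#' * S4: one informed high-confidence speaker, three uninformed low-confidence
#'   non-speakers.
#' * S5: informed high-confidence speaker, uninformed low-confidence speaker,
#'   two non-speakers.
#' * S6: informed high-confidence speaker, uninformed high-confidence
#'   speaker, two non-speakers.
#' * S7: informed low-confidence speaker, uninformed high-confidence speaker,
#'   two non-speakers.
#'
#' @param id Scenario number, 1 to 7.
#' @param robustness If `TRUE`, use the increased social-uncertainty trust
#'   range (upper bound 0.80 instead of 0.94).
#' @param replications Number of replicate runs in a batch.
#' @param base_seed Base seed for the batch.
#' @param trust_range Override of the initial trust range (takes precedence
#'   over `robustness`).
#' @param scenario_id Override of the default `"S<id>"` label.
#' @param ... Further arguments passed to [scenario_config()] (e.g.
#'   `uninformed_range`).
#' @return A [scenario_config()] object.
#' @export
scenario <- function(id, robustness = FALSE, replications = 5000,
                     base_seed = 1L, trust_range = NULL, scenario_id = NULL,
                     ...) {
  if (length(id) != 1 || !id %in% 1:7) {
    stop("unknown scenario id: ", id, " (must be 1-7)", call. = FALSE)
  }
  hi <- 0.8
  lo <- 0.2
  agent <- function(informed, confidence, speaks) {
    data.frame(informed = informed, confidence = confidence,
               social_skills = as.numeric(speaks), social_preferences = TRUE)
  }
  agents <- switch(as.character(id),
    "1" = rbind(agent(FALSE, lo, TRUE), agent(FALSE, lo, TRUE),
                agent(FALSE, lo, TRUE), agent(FALSE, lo, TRUE)),
    "2" = rbind(agent(TRUE, hi, TRUE), agent(FALSE, lo, TRUE),
                agent(FALSE, lo, TRUE), agent(FALSE, lo, TRUE)),
    "3" = rbind(agent(TRUE, hi, TRUE), agent(TRUE, hi, TRUE),
                agent(FALSE, lo, TRUE), agent(FALSE, lo, TRUE)),
    "4" = rbind(agent(TRUE, hi, TRUE), agent(FALSE, lo, FALSE),
                agent(FALSE, lo, FALSE), agent(FALSE, lo, FALSE)),
    "5" = rbind(agent(TRUE, hi, TRUE), agent(FALSE, lo, TRUE),
                agent(FALSE, lo, FALSE), agent(FALSE, lo, FALSE)),
    "6" = rbind(agent(TRUE, hi, TRUE), agent(FALSE, hi, TRUE),
                agent(FALSE, lo, FALSE), agent(FALSE, lo, FALSE)),
    "7" = rbind(agent(TRUE, lo, TRUE), agent(FALSE, hi, TRUE),
                agent(FALSE, lo, FALSE), agent(FALSE, lo, FALSE))
  )
  scenario_config(
    agents,
    scenario_id = scenario_id %||%
      paste0("S", id, if (robustness) "-robust"),
    trust_range = trust_range %||%
      c(0.66, if (robustness) 0.80 else 0.94),
    replications = replications,
    base_seed = base_seed,
    ...
  )
}
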