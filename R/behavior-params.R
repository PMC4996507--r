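#' Behavioral parameters of the agent model
#'
#' All free behavioral constants of the decision model in one validated
#' container. The model's qualitative assumptions fix only directions
#' (monotonicity and proportionality); these parameters pin down the
#' magnitudes, and every one of them can be overridden in a run
#' configuration.
#'
#' @param update_probability Baseline probability that an agent revisits its
#'   knowledge when a group agreement exists. The effective per-tick update
#'   probability is `update_probability * (1 - confidence)`: confident agents
#'   rarely reconsider.
#' @param greed_factor Multiplier (>= 1) on the equal share for agents
#'   without social preferences; their individual extraction is
#'   `min(surplus, greed_factor * surplus / n_agents)`, strictly above the
#'   equal share whenever there is a surplus and `greed_factor > 1`.
#' @param reward_increment Additive gain in confidence and trust when the
#'   observed stock matches the expectation (within `match_tolerance`).
#' @param penalty_rate Loss per unit of normalized deviation: a deviation of
#'   `d` stock units costs `penalty_rate * |d| / capacity` confidence (and,
#'   for negative deviations, trust).
#' @param match_tolerance Stock deviation (in units) within which observed
#'   and expected stock count as a match.
#' @param defection_gap_scale Scale (in extraction units) of the temptation
#'   to defect. When an agent's individual extraction level exceeds the group
#'   share by `gap`, an agent with social preferences cooperates with
#'   probability `x ^ ((gap / defection_gap_scale) ^ defection_gap_exponent)`
#'   where `x` is the trust level rescaled between `trust_floor` and
#'   `trust_ceiling`: the probability is 1 at zero gap, increases with trust,
#'   and falls with the payoff advantage of defecting. See the methods
#'   vignette for the calibration of this default.
#' @param defection_gap_exponent Exponent on the normalized temptation gap in
#'   the cooperation probability.
#' @param trust_floor Minimum trust for conditional cooperation: trust is
#'   rescaled to `(trust - trust_floor) / (trust_ceiling - trust_floor)`
#'   (clamped to `[0, 1]`) before entering the cooperation probability, so an
#'   agent whose trust is at or below the floor never sticks to an agreement
#'   that pays less than its individual level.
#' @param trust_ceiling Trust level of certain cooperation: an agent whose
#'   trust is at or above the ceiling always honors an agreement. Between the
#'   floor and the ceiling cooperation is probabilistic. See the methods
#'   vignette for the calibration of this default.
#' @param knowledge_range Admissible range of the perceived optimal stock
#'   size; knowledge is clamped to it after every update.
#'
#' @return An object of class `behavior_params` (a validated list).
#' @export
behavior_params <- function(update_probability = 0.5,
                            greed_factor = 2,
                            reward_increment = 0.05,
                            penalty_rate = 0.5,
                            match_tolerance = 0.5,
                            defection_gap_scale = 4.5,
                            defection_gap_exponent = 1,
                            trust_floor = 0,
                            trust_ceiling = 0.8,
                            knowledge_range = c(5, 50)) {
  stopifnot(
    update_probability >= 0, update_probability <= 1,
    greed_factor >= 1,
    reward_increment >= 0,
    penalty_rate >= 0,
    match_tolerance >= 0,
    defection_gap_scale > 0,
    defection_gap_exponent > 0,
    trust_floor >= 0, trust_floor < 1,
    trust_ceiling > trust_floor, trust_ceiling <= 1,
    length(knowledge_range) == 2, knowledge_range[1] < knowledge_range[2]
  )
  structure(
    list(
      update_probability = update_probability,
      greed_factor = greed_factor,
      reward_increment = reward_increment,
      penalty_rate = penalty_rate,
      match_tolerance = match_tolerance,
      defection_gap_scale = defection_gap_scale,
      defection_gap_exponent = defection_gap_exponent,
      trust_floor = trust_floor,
      trust_ceiling = trust_ceiling,
      knowledge_range = as.numeric(knowledge_range)
    ),
    class = "behavior_params"
  )
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("Behavioral parameters:\n")
  for (nm in setdiff(names(x), "knowledge_range")) {
    cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-20s [%g, %g]\n", "knowledge_range",
              x$knowledge_range[1], x$knowledge_range[2]))
  invisible(x)
}
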