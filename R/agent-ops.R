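#' Agent decision operators
#'
#' These functions implement the per-tick decisions of a single agent (or,
#' vectorised, of all agents at once): whether to speak up, how the group
#' agreement forms from the communicated knowledge, how individual knowledge
#' is updated toward the agreement, how individual and group extraction
#' levels are computed, how the agent chooses between them, and how
#' confidence and trust respond to ecological feedback. All randomness uses
#' R's global random number stream; callers seed it per run.
#'
#' @name agent-ops
NULL

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Decide whether agents speak up
#'
#' Speaking up and sharing knowledge is more likely for agents with high
#' social skills: each agent speaks with probability equal to its
#' `social_skills` value (a Bernoulli draw per agent).
#'
#' @param social_skills Speaking probabilities in `[0, 1]`. Vectorised.
#' @return Logical vector: which agents spoke this tick.
#' @export
decide_speak <- function(social_skills) {
  stats::runif(length(social_skills)) < social_skills
}

#' Form group knowledge from the speakers' communicated knowledge
#'
#' The group's perception of the optimal stock size is the average of all
#' communicated individual knowledge, weighted by each speaker's confidence:
#' the more confidently an agent shares its knowledge, the more influence it
#' has on the agreement. With no speakers there is no agreement (`NA`); if
#' all speaking confidences are zero the unweighted mean is used (the limit
#' of equal weights).
#'
#' @param knowledge Speakers' perceived optimal stock sizes.
#' @param confidence Speakers' confidence values, >= 0, same length.
#' @return The group knowledge, or `NA_real_` if there are no speakers.
#' @export
form_group_knowledge <- function(knowledge, confidence) {
  stopifnot(length(knowledge) == length(confidence))
  if (length(knowledge) == 0) return(NA_real_)
  if (any(confidence < 0)) stop("confidence must be non-negative", call. = FALSE)
  w <- sum(confidence)
  if (w == 0) mean(knowledge) else sum(confidence * knowledge) / w
}

#' Update individual knowledge toward the group knowledge
#'
#' With probability `update_probability * (1 - confidence)` an agent moves
#' its knowledge a partial step of size `(1 - confidence)` toward the group
#' knowledge: the lower the confidence, the more likely and the larger the
#' revision. The move never overshoots the group knowledge, and the result is
#' clamped to the admissible knowledge range. With no agreement, knowledge is
#' unchanged.
#'
#' @param knowledge Current perceived optimal stock sizes. Vectorised over
#'   agents.
#' @param confidence Confidence values in `[0, 1]`, same length.
#' @param group_knowledge Group knowledge, or `NA` when no agreement exists.
#' @param params A [behavior_params()] object.
#' @return Updated knowledge vector.
#' @export
update_knowledge <- function(knowledge, confidence, group_knowledge, params) {
  n <- length(knowledge)
  u <- stats::runif(n)  # drawn unconditionally so the stream is order-stable
  if (is.na(group_knowledge)) return(knowledge)
  fires <- u < params$update_probability * (1 - confidence)
  step <- (1 - confidence) * (group_knowledge - knowledge)
  out <- ifelse(fires, knowledge + step, knowledge)
  .clamp(out, params$knowledge_range[1], params$knowledge_range[2])
}

#' Individual extraction level
#'
#' The amount an agent would extract to bring the stock down to its own
#' perceived optimal stock size. Below the perceived optimum the extraction
#' is zero. An agent with social preferences claims an equal share of the
#' perceived surplus; an agent without social preferences claims
#' `greed_factor` times the equal share (capped at the whole surplus),
#' strictly more than the equal share whenever there is a surplus.
#'
#' @param knowledge Perceived optimal stock size(s). Vectorised over agents.
#' @param stock Current stock size, >= 0.
#' @param n_agents Number of agents in the group, >= 1.
#' @param social_preferences Logical: preference for equal sharing.
#' @param params A [behavior_params()] object.
#' @return Individual extraction level(s), >= 0.
#' @export
individual_extraction <- function(knowledge, stock, n_agents,
                                  social_preferences,
                                  params = behavior_params()) {
  stopifnot(stock >= 0, n_agents >= 1)
  surplus <- pmax(0, stock - knowledge)
  equal <- surplus / n_agents
  ifelse(social_preferences, equal,
         pmin(surplus, params$greed_factor * equal))
}

#' Group extraction level implied by the group agreement
#'
#' The group extracts the surplus above the optimal stock size reflected in
#' the group knowledge, shared equally among all members.
#'
#' @param group_knowledge Group knowledge (must not be `NA`).
#' @param stock Current stock size, >= 0.
#' @param n_agents Number of agents, >= 1.
#' @return List with `total` and per-agent `share`.
#' @export
group_extraction <- function(group_knowledge, stock, n_agents) {
  stopifnot(!is.na(group_knowledge), stock >= 0, n_agents >= 1)
  total <- max(0, stock - group_knowledge)
  list(total = total, share = total / n_agents)
}

#' Probability that an agent sticks to the group agreement
#'
#' Applies only when the agent's individual extraction level exceeds the
#' group share (otherwise the group level is chosen outright). An agent with
#' social preferences is a conditional cooperator: it follows the agreement
#' with probability `trust ^ ((gap / defection_gap_scale) ^ 2)`, where `gap`
#' is the payoff advantage of defecting (individual level minus group share).
#' Full trust always yields cooperation; at zero trust any positive gap
#' yields defection; for a fixed trust below 1, the cooperation probability
#' decreases as the temptation grows.
#'
#' @param trust Trust in `[0, 1]`. Vectorised.
#' @param gap Individual extraction level minus group share, > 0.
#' @param params A [behavior_params()] object.
#' @return Cooperation probability in `[0, 1]`.
#' @export
cooperation_probability <- function(trust, gap, params = behavior_params()) {
  w <- (pmax(gap, 0) / params$defection_gap_scale)^params$defection_gap_exponent
  x <- pmax(0, (trust - params$trust_floor) /
              (params$trust_ceiling - params$trust_floor))
  ifelse(x >= 1, 1, ifelse(x <= 0, as.numeric(w == 0), x^w))
}

#' Choose between the group and the individual extraction level
#'
#' If the group share is at least the agent's individual level, every agent
#' chooses the group level (it pays at least as much and keeps the
#' agreement). Otherwise an agent with social preferences cooperates with
#' the probability given by [cooperation_probability()]; an agent without
#' social preferences takes its individual level. With no group agreement
#' every agent takes its individual level.
#'
#' @param individual_level Individual extraction level(s), >= 0. Vectorised
#'   over agents.
#' @param group_share Per-agent group share, or `NA` when no agreement
#'   exists.
#' @param trust Trust values in `[0, 1]`, same length.
#' @param social_preferences Logical vector, same length.
#' @param params A [behavior_params()] object.
#' @return List with `extraction` (chosen level per agent) and `chose_group`
#'   (logical per agent).
#' @export
choose_extraction <- function(individual_level, group_share, trust,
                              social_preferences,
                              params = behavior_params()) {
  n <- length(individual_level)
  u <- stats::runif(n)  # unconditional draw keeps the stream order-stable
  if (is.na(group_share)) {
    return(list(extraction = individual_level, chose_group = rep(FALSE, n)))
  }
  gap <- individual_level - group_share
  p_coop <- cooperation_probability(trust, gap, params)
  cooperate <- gap <= 0 | (social_preferences & u < p_coop)
  list(
    extraction = ifelse(cooperate, group_share, individual_level),
    chose_group = cooperate
  )
}

#' Stock an agent expects to observe after the tick
#'
#' Under the default "true dynamics" expectation mode the agent assumes that
#' every other group member complies with the agreement (extracts the group
#' share) and knows the true regeneration table (the growth chart is public):
#' the expected stock is the ecological step applied to the agent's own
#' planned extraction plus `n_agents - 1` group shares. An agent's own
#' defection is part of its own plan, so it creates no deviation for that
#' agent. With no agreement the expectation is undefined (`NA`) and no
#' feedback update takes place.
#'
#' @param table A [regen_table()] object.
#' @param stock Pre-extraction stock size.
#' @param own_extraction The agent's own chosen extraction. Vectorised over
#'   agents.
#' @param group_share Per-agent group share, or `NA`.
#' @param n_agents Number of agents in the group.
#' @return Expected stock size(s), or `NA` when no agreement exists.
#' @export
expected_stock <- function(table, stock, own_extraction, group_share, n_agents) {
  if (is.na(group_share)) return(rep(NA_real_, length(own_extraction)))
  planned <- own_extraction + (n_agents - 1) * group_share
  resource_step(table, stock, planned)
}

#' Update confidence and trust from ecological feedback
#'
#' Compares the observed stock with the expectation. A match (absolute
#' deviation within `match_tolerance`) reassures the agent: confidence and
#' trust both increase by `reward_increment`. A positive deviation (more
#' stock than expected) can only stem from misunderstanding the resource:
#' confidence drops in proportion to the deviation, trust is unchanged. A
#' negative deviation (less stock than expected) may mean someone took more
#' than agreed or the agent misjudged the dynamics: both confidence and trust
#' drop in proportion to the deviation. Losses are
#' `penalty_rate * |deviation| / capacity`; all values are clamped to
#' `[0, 1]`. With an undefined expectation (`NA`) nothing changes.
#'
#' @param confidence Confidence values in `[0, 1]`. Vectorised over agents.
#' @param trust Trust values in `[0, 1]`, same length.
#' @param expected Expected stock size(s) (possibly `NA`).
#' @param actual Observed stock size.
#' @param params A [behavior_params()] object.
#' @param capacity Carrying capacity used to normalize deviations.
#' @return List with updated `confidence` and `trust`.
#' @export
update_confidence_trust <- function(confidence, trust, expected, actual,
                                    params = behavior_params(),
                                    capacity = 50) {
  stopifnot(actual >= 0)
  d <- actual - expected
  loss <- params$penalty_rate * abs(d) / capacity
  conf_new <- ifelse(
    is.na(d), confidence,
    ifelse(abs(d) <= params$match_tolerance,
           confidence + params$reward_increment,
           confidence - loss)
  )
  trust_new <- ifelse(
    is.na(d), trust,
    ifelse(abs(d) <= params$match_tolerance,
           trust + params$reward_increment,
           ifelse(d < 0, trust - loss, trust))
  )
  list(confidence = .clamp(conf_new, 0, 1), trust = .clamp(trust_new, 0, 1))
}
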