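#' One simulated tick of the harvesting game
#'
#' Executes the fixed per-tick process order on a group state: all agents
#' decide whether to speak (in ascending agent order), the group knowledge is
#' formed from the speakers, every agent may update its individual knowledge
#' toward it, the group and individual extraction levels are computed (the
#' individual level from the post-update knowledge), every agent chooses its
#' level, over-demand is rationed proportionally, the resource is harvested
#' and regenerates, and finally each agent compares the reported stock with
#' its expectation and updates confidence and trust. All random draws come
#' from R's global stream in this fixed order, so a seeded run is exactly
#' reproducible.
#'
#' @param state A group state as produced by [init_state()] or a previous
#'   `simulate_tick()` call.
#' @param table A [regen_table()] object.
#' @param params A [behavior_params()] object.
#' @return The updated state. Per-tick quantities of the executed tick are in
#'   the `last` field.
#' @export
simulate_tick <- function(state, table, params = behavior_params()) {
  n <- state$n_agents
  stock <- state$stock

  spoke <- decide_speak(state$social_skills)
  gk <- form_group_knowledge(state$knowledge[spoke], state$confidence[spoke])

  knowledge <- update_knowledge(state$knowledge, state$confidence, gk, params)

  if (is.na(gk)) {
    g_total <- NA_real_
    g_share <- NA_real_
  } else {
    g <- group_extraction(gk, stock, n)
    g_total <- g$total
    g_share <- g$share
  }
  ind <- individual_extraction(knowledge, stock, n,
                               state$social_preferences, params)
  choice <- choose_extraction(ind, g_share, state$trust,
                              state$social_preferences, params)
  chosen <- choice$extraction

  # proportional rationing when demand exceeds the available stock
  demand <- sum(chosen)
  realized <- if (demand > stock && demand > 0) chosen * stock / demand else chosen
  total_extraction <- sum(realized)
  post_harvest <- max(0, stock - total_extraction)
  new_stock <- resource_step(table, stock, total_extraction)

  expected <- expected_stock(table, stock, chosen, g_share, n)
  upd <- update_confidence_trust(state$confidence, state$trust,
                                 expected, new_stock, params,
                                 capacity = table$capacity)

  if (any(knowledge < params$knowledge_range[1] - 1e-9) ||
      any(knowledge > params$knowledge_range[2] + 1e-9) ||
      new_stock < -1e-9 || new_stock > table$capacity + 1e-9) {
    stop("state invariant violated during tick: knowledge or stock out of bounds",
         call. = FALSE)
  }

  state$knowledge <- knowledge
  state$confidence <- upd$confidence
  state$trust <- upd$trust
  state$stock <- new_stock
  state$last <- list(
    spoke = spoke,
    group_knowledge = gk,
    group_total = g_total,
    group_share = g_share,
    individual_level = ind,
    chosen_extraction = chosen,
    realized_extraction = realized,
    chose_group = choice$chose_group,
    total_extraction = total_extraction,
    post_harvest = post_harvest,
    expected_stock = expected,
    stock_reported = new_stock
  )
  state
}

#' Initialize a group state from a scenario configuration
#'
#' Draws the initial agent states from the configuration's ranges using the
#' current random stream: integer-uniform knowledge from the informed or
#' uninformed range (one draw per agent, in agent order), then real-uniform
#' trust from the trust range (one draw per agent).
#'
#' @param config A [scenario_config()] object.
#' @return A group state list consumed by [simulate_tick()].
#' @export
init_state <- function(config) {
  a <- config$agents
  n <- nrow(a)
  draw_int <- function(r) pmin(r[1] + floor(stats::runif(1) * (r[2] - r[1] + 1)), r[2])
  knowledge <- vapply(seq_len(n), function(i) {
    draw_int(if (a$informed[i]) config$informed_range else config$uninformed_range)
  }, numeric(1))
  trust <- config$trust_range[1] +
    stats::runif(n) * diff(config$trust_range)
  list(
    n_agents = n,
    stock = config$initial_stock,
    knowledge = knowledge,
    confidence = a$confidence,
    trust = trust,
    social_skills = a$social_skills,
    social_preferences = a$social_preferences,
    last = NULL
  )
}

#' Run one full game
#'
#' Seeds the random stream, draws the initial agent states from the
#' configuration ranges, and executes `n_ticks` ticks. The same seed always
#' yields an identical result.
#'
#' @param config A [scenario_config()] object.
#' @param table A [regen_table()] object.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed for this run.
#' @return An object of class `cpr_run`: a list with `config`, `seed`, a
#'   tick-level data frame `ticks` (stock at tick start, group knowledge and
#'   shares, total extraction, post-harvest and reported stock) and an
#'   agent-level data frame `agents` (one row per tick and agent with the
#'   decisions and the end-of-tick knowledge, confidence and trust).
#' @export
simulate_run <- function(config, table = default_regen_table(),
                         params = behavior_params(), seed = config$base_seed) {
  set.seed(as.integer(seed))
  state <- init_state(config)
  n <- state$n_agents
  nt <- config$n_ticks

  tick_mat <- matrix(NA_real_, nrow = nt, ncol = 7)
  colnames(tick_mat) <- c("stock_start", "group_knowledge", "group_total",
                          "group_share", "total_extraction", "post_harvest",
                          "stock_reported")
  ag_num <- array(NA_real_, dim = c(nt, n, 6))
  ag_lgl <- array(NA, dim = c(nt, n, 2))

  for (t in seq_len(nt)) {
    stock_start <- state$stock
    state <- simulate_tick(state, table, params)
    l <- state$last
    tick_mat[t, ] <- c(stock_start, l$group_knowledge, l$group_total,
                       l$group_share, l$total_extraction, l$post_harvest,
                       l$stock_reported)
    ag_num[t, , ] <- cbind(state$knowledge, state$confidence, state$trust,
                           l$chosen_extraction, l$realized_extraction,
                           l$expected_stock)
    ag_lgl[t, , ] <- cbind(l$spoke, l$chose_group)
  }

  ticks <- data.frame(tick = seq_len(nt), tick_mat)
  agents <- data.frame(
    tick = rep(seq_len(nt), each = n),
    agent_id = rep(seq_len(n), times = nt),
    knowledge = as.vector(t(ag_num[, , 1])),
    confidence = as.vector(t(ag_num[, , 2])),
    trust = as.vector(t(ag_num[, , 3])),
    chosen_extraction = as.vector(t(ag_num[, , 4])),
    realized_extraction = as.vector(t(ag_num[, , 5])),
    expected_stock = as.vector(t(ag_num[, , 6])),
    spoke = as.vector(t(ag_lgl[, , 1])),
    chose_group = as.vector(t(ag_lgl[, , 2]))
  )
  structure(
    list(config = config, seed = as.integer(seed), ticks = ticks,
         agents = agents),
    class = "cpr_run"
  )
}

#' @export
print.cpr_run <- function(x, ...) {
  cat(sprintf("Run of scenario '%s' (seed %d, %d ticks)\n",
              x$config$scenario_id, x$seed, nrow(x$ticks)))
  cat("Reported stock:", paste(round(x$ticks$stock_reported, 1), collapse = " "),
      "\n")
  invisible(x)
}

#' Run replicated games and summarize them
#'
#' Runs `config$replications` independent games with seeds `base_seed + 1`,
#' `base_seed + 2`, ... and collects per-run classifications and the per-tick
#' mean of the reported stock (the scenario curves of the group-composition
#' experiments).
#'
#' @param config A [scenario_config()] object.
#' @param table A [regen_table()] object.
#' @param params A [behavior_params()] object.
#' @param keep_runs If `TRUE`, retain every full `cpr_run` (memory-hungry for
#'   large batches).
#' @param coop_fraction_threshold Fraction of fully cooperative runs above
#'   which the configuration as a whole is classified cooperative.
#' @param class_tolerance Stock tolerance (units) around the MSY bin used by
#'   [classify_exploitation()].
#' @return An object of class `cpr_batch`: a list with `config`, a run-level
#'   data frame `run_stats` (cooperative flag, exploitation class, learning
#'   slope, mean distance of the reported stock from the MSY stock band),
#'   `mean_stock` (per-tick mean reported stock), `cooperative_fraction`,
#'   `config_cooperative`, `exploitation_freq`, and optionally `runs`.
#' @export
simulate_batch <- function(config, table = default_regen_table(),
                           params = behavior_params(), keep_runs = FALSE,
                           coop_fraction_threshold = 0.9,
                           class_tolerance = 2) {
  reps <- config$replications
  policy <- optimal_policy_vector(table)
  band <- msy_stock_band(table)
  stock_sum <- numeric(config$n_ticks)
  runs <- if (keep_runs) vector("list", reps) else NULL
  stats_df <- data.frame(
    run = seq_len(reps),
    seed = config$base_seed + seq_len(reps),
    cooperative = NA,
    exploitation = NA_character_,
    learning_slope = NA_real_,
    mean_band_distance = NA_real_
  )
  for (i in seq_len(reps)) {
    r <- simulate_run(config, table, params, seed = config$base_seed + i)
    if (keep_runs) runs[[i]] <- r
    stock_sum <- stock_sum + r$ticks$stock_reported
    dev <- deviation_series(r, table, policy = policy)
    stats_df$cooperative[i] <- classify_cooperation(r)
    stats_df$exploitation[i] <- classify_exploitation(r, table,
                                                      tolerance = class_tolerance)
    stats_df$learning_slope[i] <- learning_trend(dev)
    s <- r$ticks$stock_reported
    stats_df$mean_band_distance[i] <- mean(pmax(0, band[1] - s, s - band[2]))
  }
  coop_frac <- mean(stats_df$cooperative)
  structure(
    list(
      config = config,
      runs = runs,
      run_stats = stats_df,
      mean_stock = stock_sum / reps,
      cooperative_fraction = coop_frac,
      config_cooperative = coop_frac >= coop_fraction_threshold,
      exploitation_freq = prop.table(base::table(factor(
        stats_df$exploitation, levels = c("over", "optimal", "under"))))
    ),
    class = "cpr_batch"
  )
}

#' @export
print.cpr_batch <- function(x, ...) {
  cat(sprintf("Batch of %d runs, scenario '%s'\n",
              nrow(x$run_stats), x$config$scenario_id))
  cat(sprintf("  cooperative runs: %.1f%% (configuration %s)\n",
              100 * x$cooperative_fraction,
              if (x$config_cooperative) "cooperative" else "non-cooperative"))
  cat("  exploitation classes:",
      paste(sprintf("%s %.1f%%", names(x$exploitation_freq),
                    100 * as.numeric(x$exploitation_freq)), collapse = ", "),
      "\n")
  cat("  mean reported stock:",
      paste(round(x$mean_stock, 1), collapse = " "), "\n")
  invisible(x)
}
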