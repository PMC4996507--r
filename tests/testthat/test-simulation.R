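tab <- default_regen_table()
params <- behavior_params()

# a homogeneous group: all informed at exactly the bin lower edge, all speak
uniform_group <- function(knowledge = 25, confidence = 0.5, skills = 1,
                          prefs = TRUE, n = 4, ...) {
  scenario_config(
    data.frame(informed = TRUE, confidence = confidence,
               social_skills = skills, social_preferences = prefs)[rep(1, n), ],
    informed_range = c(knowledge, knowledge),
    replications = 1,
    ...
  )
}

test_that("identical informed agents harvest the surplus and hit the MSY cycle", {
  cfg <- uniform_group(knowledge = 25)
  r <- simulate_run(cfg, tab, params, seed = 3)
  expect_equal(r$ticks$group_knowledge[1], 25)
  expect_equal(r$ticks$total_extraction[1], 25)
  expect_equal(r$ticks$stock_reported[1], 34)
  # afterwards the group sits on the 34 -> 25 -> 34 cycle extracting the MSY
  expect_equal(r$ticks$total_extraction[-1], rep(9, 13))
  expect_equal(r$ticks$stock_reported[-1], rep(34, 13))
  expect_true(classify_cooperation(r))
})

test_that("full compliance makes trust and confidence non-decreasing", {
  cfg <- uniform_group(knowledge = 27, confidence = 0.3)
  r <- simulate_run(cfg, tab, params, seed = 11)
  for (id in 1:4) {
    a <- r$agents[r$agents$agent_id == id, ]
    expect_true(all(diff(a$trust) >= 0))
    expect_true(all(diff(a$confidence) >= 0))
  }
})

test_that("seeded runs replay bit-identically and seeds matter", {
  cfg <- scenario(5, replications = 1, base_seed = 1)
  r1 <- simulate_run(cfg, tab, params, seed = 123)
  r2 <- simulate_run(cfg, tab, params, seed = 123)
  expect_identical(r1, r2)
  r3 <- simulate_run(cfg, tab, params, seed = 124)
  expect_false(identical(r1$ticks, r3$ticks))
})

test_that("runs respect the stock bounds on every tick", {
  for (id in c(1, 4, 7)) {
    cfg <- scenario(id, replications = 1)
    for (seed in 1:5) {
      r <- simulate_run(cfg, tab, params, seed = seed)
      expect_true(all(r$ticks$stock_reported >= 0 &
                        r$ticks$stock_reported <= 50))
      expect_true(all(r$agents$chosen_extraction >= 0))
    }
  }
})

test_that("a silent group never forms an agreement", {
  cfg <- scenario_config(
    data.frame(informed = FALSE, confidence = 0.2, social_skills = 0,
               social_preferences = TRUE)[rep(1, 4), ]
  )
  r <- simulate_run(cfg, tab, params, seed = 2)
  expect_true(all(is.na(r$ticks$group_knowledge)))
  expect_false(any(r$agents$chose_group))
  expect_false(classify_cooperation(r))
  # without feedback expectations, confidence and trust stay at their draws
  expect_equal(length(unique(r$agents$trust[r$agents$agent_id == 1])), 1)
})

test_that("over-demand is rationed proportionally to the claims", {
  state <- list(
    n_agents = 4, stock = 20,
    knowledge = rep(5, 4), confidence = rep(0.5, 4),
    trust = rep(0.5, 4), social_skills = rep(0, 4),
    social_preferences = rep(FALSE, 4), last = NULL
  )
  greedy <- behavior_params(greed_factor = 10)
  set.seed(9)
  st <- simulate_tick(state, tab, greedy)
  l <- st$last
  # each claims the whole perceived surplus of 15; only 20 units exist
  expect_equal(l$chosen_extraction, rep(15, 4))
  expect_equal(l$realized_extraction, rep(5, 4))
  expect_equal(l$total_extraction, 20)
  expect_equal(st$stock, 0)  # post-harvest 0 and no regeneration below 5
})

test_that("the seven published compositions are encoded faithfully", {
  speakers <- vapply(1:7, function(id) sum(scenario(id)$agents$social_skills == 1),
                     numeric(1))
  expect_equal(speakers, c(4, 4, 4, 1, 2, 2, 2))
  informed <- vapply(1:7, function(id) sum(scenario(id)$agents$informed),
                     numeric(1))
  expect_equal(informed, c(0, 1, 2, 1, 1, 1, 1))
  for (id in 1:7) {
    cfg <- scenario(id)
    a <- cfg$agents
    expect_true(all(a$social_preferences))
    expect_equal(cfg$trust_range, c(0.66, 0.94))
    expect_gte(sum(a$social_skills == 1), 1)
    # non-speakers are uninformed with low confidence
    ns <- a$social_skills == 0
    expect_true(all(!a$informed[ns]))
    expect_true(all(a$confidence[ns] == 0.2))
  }
  # the informed agent is confident in scenarios 4-6 but not in 7
  expect_equal(scenario(6)$agents$confidence[scenario(6)$agents$informed], 0.8)
  expect_equal(scenario(7)$agents$confidence[scenario(7)$agents$informed], 0.2)
  # robustness variant caps the trust draw at 0.8
  expect_equal(scenario(4, robustness = TRUE)$trust_range, c(0.66, 0.80))
  expect_error(scenario(99), "unknown scenario")
})

test_that("initial states are drawn from the configured ranges", {
  cfg <- scenario(2)
  set.seed(31)
  ks <- replicate(300, init_state(cfg)$knowledge)
  expect_true(all(ks[1, ] >= 25 & ks[1, ] <= 29))       # informed agent
  expect_true(all(ks[2:4, ] >= 10 & ks[2:4, ] <= 24))   # uninformed agents
  expect_true(all(ks == floor(ks)))                      # integer draws
  expect_setequal(unique(as.vector(ks[1, ])), 25:29)
  set.seed(31)
  tr <- replicate(300, init_state(cfg)$trust)
  expect_true(all(tr >= 0.66 & tr <= 0.94))
})

test_that("an informed confident speaker lifts the first-tick agreement", {
  gk1 <- function(id) {
    cfg <- scenario(id, replications = 1)
    mean(vapply(1:100, function(s) {
      simulate_run(cfg, tab, params, seed = 1000 + s)$ticks$group_knowledge[1]
    }, numeric(1)))
  }
  g1 <- gk1(1)
  g2 <- gk1(2)
  expect_lt(g2, 25)  # still slightly below the optimal stock size
  expect_gt(g2, g1)  # but well above the all-uninformed agreement
})

test_that("batches aggregate runs reproducibly", {
  cfg <- scenario(3, replications = 40, base_seed = 77)
  b1 <- simulate_batch(cfg, tab, params)
  b2 <- simulate_batch(cfg, tab, params)
  expect_identical(b1$run_stats, b2$run_stats)
  expect_equal(nrow(b1$run_stats), 40)
  # a one-replication batch is the summary of that single run
  cfg1 <- scenario(3, replications = 1, base_seed = 77)
  b <- simulate_batch(cfg1, tab, params, keep_runs = TRUE)
  r <- simulate_run(cfg1, tab, params, seed = 78)
  expect_identical(b$runs[[1]], r)
  expect_equal(b$mean_stock, r$ticks$stock_reported)
  expect_equal(b$cooperative_fraction, as.numeric(classify_cooperation(r)))
})

test_that("batch means are stable across replication counts", {
  m <- function(reps, seed) {
    cfg <- scenario(2, replications = reps, base_seed = seed)
    b <- simulate_batch(cfg, tab, params)
    b$mean_stock
  }
  m1 <- m(250, 500)
  m2 <- m(500, 9000)
  # per-tick reported stock has sd well under 8 units; allow 4 standard
  # errors of the smaller batch
  expect_true(all(abs(m1 - m2) < 4 * 8 / sqrt(250)))
})

test_that("configuration validation reports every violated field", {
  msg <- tryCatch(
    scenario_config(
      data.frame(informed = TRUE, confidence = 2, social_skills = 1,
                 social_preferences = TRUE),
      trust_range = c(0.9, 0.6), n_ticks = 0
    ),
    error = conditionMessage
  )
  expect_match(msg, "confidence")
  expect_match(msg, "trust_range")
  expect_match(msg, "n_ticks")
  expect_error(scenario_config(data.frame(x = 1)), "missing column")
})
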