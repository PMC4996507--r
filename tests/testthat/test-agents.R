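params <- behavior_params()

test_that("speaking is a Bernoulli draw driven by social skills", {
  set.seed(1)
  expect_true(all(replicate(50, decide_speak(rep(1, 4)))))
  expect_false(any(replicate(50, decide_speak(rep(0, 4)))))
  draws <- replicate(10000, decide_speak(0.5))
  # binomial sampling bound: 0.5 +/- 3 sigma
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("group knowledge is the confidence-weighted mean of the speakers", {
  expect_equal(form_group_knowledge(27, 0.8), 27)
  # one confident informed speaker against three unconfident uninformed ones
  expect_equal(
    form_group_knowledge(c(27, 17, 17, 17), c(0.8, 0.2, 0.2, 0.2)),
    (0.8 * 27 + 3 * 0.2 * 17) / 1.4
  )
  expect_equal(form_group_knowledge(c(10, 20, 30), rep(0.7, 3)), 20)
  expect_true(is.na(form_group_knowledge(numeric(0), numeric(0))))
  # all-zero confidence falls back to the unweighted mean
  expect_equal(form_group_knowledge(c(10, 30), c(0, 0)), 20)
  expect_error(form_group_knowledge(10, -0.1), "non-negative")
})

test_that("group knowledge stays within the speakers' range and moves toward confident speakers", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    k <- runif(n, 5, 50)
    cf <- runif(n)
    gk <- form_group_knowledge(k, cf)
    expect_gte(gk, min(k) - 1e-12)
    expect_lte(gk, max(k) + 1e-12)
    # raising one speaker's confidence pulls the agreement toward them
    j <- sample(n, 1)
    cf2 <- cf
    cf2[j] <- cf[j] + 0.3
    gk2 <- form_group_knowledge(k, cf2)
    expect_lte(abs(gk2 - k[j]), abs(gk - k[j]) + 1e-12)
  }
})

test_that("knowledge updates move partially toward the agreement and never past it", {
  # certain agents never move: update probability and step size are both 0
  set.seed(7)
  expect_equal(update_knowledge(17, 1, 30, params), 17)
  # update at low confidence: 17 + 0.8 * (22.714 - 17)
  # (seed 1 makes the update fire: first uniform draw 0.266 < 0.8)
  p_always <- behavior_params(update_probability = 1)
  gk <- (0.8 * 27 + 3 * 0.2 * 17) / 1.4
  set.seed(1)
  expect_equal(update_knowledge(17, 0.2, gk, p_always), 17 + 0.8 * (gk - 17))
  # a fully unconfident agent always updates, all the way to the agreement
  set.seed(7)
  expect_equal(update_knowledge(17, 0, gk, p_always), gk)
  # no agreement: no change, for any confidence
  set.seed(7)
  expect_equal(update_knowledge(c(10, 40), c(0.1, 0.9), NA_real_, params),
               c(10, 40))
})

test_that("knowledge updating is a contraction toward group knowledge with clamping", {
  set.seed(99)
  for (i in 1:300) {
    k <- runif(4, 5, 50)
    cf <- runif(4)
    gk <- runif(1, 5, 50)
    k2 <- update_knowledge(k, cf, gk, params)
    expect_true(all(abs(k2 - gk) <= abs(k - gk) + 1e-12))
    expect_true(all(k2 >= 5 & k2 <= 50))
  }
  # clamping at the admissible range
  narrow <- behavior_params(update_probability = 1, knowledge_range = c(20, 30))
  set.seed(1)
  expect_equal(update_knowledge(30, 0, 80, narrow), 30)
})

test_that("individual extraction targets the perceived optimal stock size", {
  # stock below the perceived optimum: no extraction
  expect_equal(individual_extraction(27, 20, 4, TRUE, params), 0)
  # equal share of the perceived surplus under social preferences
  expect_equal(individual_extraction(27, 50, 4, TRUE, params), 23 / 4)
  # without social preferences: greed factor times the equal share
  expect_equal(individual_extraction(27, 50, 4, FALSE, params), 11.5)
  # greedy claim is capped at the whole surplus
  one_agent <- individual_extraction(27, 50, 1, FALSE, params)
  expect_equal(one_agent, 23)
  # strictly above the equal share whenever there is a surplus
  expect_gt(individual_extraction(27, 50, 4, FALSE, params),
            individual_extraction(27, 50, 4, TRUE, params))
})

test_that("group extraction is the equally shared surplus above the agreement", {
  gk <- (0.8 * 27 + 3 * 0.2 * 17) / 1.4
  g <- group_extraction(gk, 50, 4)
  expect_equal(g$total, 50 - gk)
  expect_equal(g$share, (50 - gk) / 4)
  expect_equal(group_extraction(30, 25, 4), list(total = 0, share = 0))
  expect_equal(group_extraction(25, 34, 4), list(total = 9, share = 2.25))
})

test_that("extraction choice follows conditional cooperation", {
  set.seed(5)
  # group level at least the individual level: group is chosen by everyone
  ch <- choose_extraction(c(5.75, 6.82), 6.82, c(0.1, 0.9), c(TRUE, FALSE), params)
  expect_equal(ch$extraction, c(6.82, 6.82))
  expect_true(all(ch$chose_group))
  # full trust: certain cooperation even when defecting pays
  set.seed(5)
  ch <- choose_extraction(10, 2, 1, TRUE, params)
  expect_equal(ch$extraction, 2)
  # zero trust: certain defection when defecting pays
  set.seed(5)
  ch <- choose_extraction(10, 2, 0, TRUE, params)
  expect_equal(ch$extraction, 10)
  expect_false(ch$chose_group)
  # no social preferences: individual level whenever it is higher
  set.seed(5)
  ch <- choose_extraction(11.5, 6.82, 0.99, FALSE, params)
  expect_equal(ch$extraction, 11.5)
  # no agreement: individual level, not counted as a group choice
  set.seed(5)
  ch <- choose_extraction(c(3, 4), NA_real_, c(1, 1), c(TRUE, TRUE), params)
  expect_equal(ch$extraction, c(3, 4))
  expect_false(any(ch$chose_group))
})

test_that("cooperation probability is monotone in trust and in the temptation gap", {
  gaps <- seq(0, 10, by = 0.5)
  trusts <- seq(0, 1, by = 0.05)
  for (tr in c(0.2, 0.66, 0.94)) {
    p <- cooperation_probability(tr, gaps, params)
    expect_true(all(diff(p) <= 1e-12))  # larger temptation, less cooperation
    expect_equal(p[1], 1)               # no temptation, no defection
  }
  for (g in c(0.5, 2, 5)) {
    p <- cooperation_probability(trusts, g, params)
    expect_true(all(diff(p) >= -1e-12)) # more trust, more cooperation
  }
  expect_equal(cooperation_probability(1, 100, params), 1)
  expect_equal(cooperation_probability(0, 1e-9, params), 0)
})

test_that("expected stock assumes others comply and uses the true dynamics", {
  tab <- default_regen_table()
  # full compliance at the agreement: expectation equals the realized stock
  share <- (50 - 25) / 4
  exp_s <- expected_stock(tab, 50, share, share, 4)
  expect_equal(exp_s, resource_step(tab, 50, 4 * share))
  # a defector's own plan contains its own defection: zero deviation for it
  own <- 10
  exp_defector <- expected_stock(tab, 50, own, share, 4)
  expect_equal(exp_defector, resource_step(tab, 50, own + 3 * share))
  # someone taking 3 units above the share pushes the stock below expectation
  actual <- resource_step(tab, 50, 4 * share + 3)
  expect_lt(actual, exp_s)
  # no agreement: expectation undefined
  expect_true(all(is.na(expected_stock(tab, 50, c(1, 2), NA_real_, 4))))
})

test_that("confidence and trust respond to ecological feedback as assumed", {
  p <- behavior_params()  # reward_increment 0.05, penalty_rate 0.5
  # match: both increase
  u <- update_confidence_trust(0.5, 0.5, 30, 30, p, capacity = 50)
  expect_equal(u, list(confidence = 0.55, trust = 0.55))
  # 10 units below expectation: both drop by 0.5 * 10 / 50 = 0.1
  u <- update_confidence_trust(0.5, 0.5, 40, 30, p, capacity = 50)
  expect_equal(u, list(confidence = 0.4, trust = 0.4))
  # above expectation: only confidence drops, trust unchanged
  u <- update_confidence_trust(0.5, 0.5, 30, 40, p, capacity = 50)
  expect_equal(u, list(confidence = 0.4, trust = 0.5))
  # clamping at the bounds
  u <- update_confidence_trust(0.02, 0.01, 50, 0, p, capacity = 50)
  expect_equal(u, list(confidence = 0, trust = 0))
  u <- update_confidence_trust(0.95, 0.99, 30, 30, p, capacity = 50)
  expect_equal(u, list(confidence = 1, trust = 1))
  # undefined expectation: no change
  u <- update_confidence_trust(0.5, 0.5, NA_real_, 30, p, capacity = 50)
  expect_equal(u, list(confidence = 0.5, trust = 0.5))
})

test_that("penalties grow strictly with the size of the deviation", {
  p <- behavior_params()
  devs <- seq(1, 30, by = 1)
  conf <- vapply(devs, function(d) {
    update_confidence_trust(1, 1, 40, 40 - d, p, capacity = 50)$confidence
  }, numeric(1))
  expect_true(all(diff(conf) < 0))
})

test_that("agent state bounds survive random operation sequences", {
  tab <- default_regen_table()
  set.seed(2024)
  for (rep in 1:50) {
    k <- runif(4, 5, 50)
    cf <- runif(4)
    tr <- runif(4)
    stock <- runif(1, 0, 50)
    for (step in 1:20) {
      spoke <- decide_speak(runif(4))
      gk <- form_group_knowledge(k[spoke], cf[spoke])
      k <- update_knowledge(k, cf, gk, params)
      share <- if (is.na(gk)) NA_real_ else group_extraction(gk, stock, 4)$share
      ind <- individual_extraction(k, stock, 4, c(TRUE, TRUE, FALSE, FALSE), params)
      ch <- choose_extraction(ind, share, tr, c(TRUE, TRUE, FALSE, FALSE), params)
      total <- min(sum(ch$extraction), stock)
      new_stock <- resource_step(tab, stock, total)
      exp_s <- expected_stock(tab, stock, ch$extraction, share, 4)
      upd <- update_confidence_trust(cf, tr, exp_s, new_stock, params)
      cf <- upd$confidence
      tr <- upd$trust
      stock <- new_stock
      expect_true(all(k >= 5 & k <= 50))
      expect_true(all(cf >= 0 & cf <= 1))
      expect_true(all(tr >= 0 & tr <= 1))
      expect_true(all(ch$extraction >= 0))
      expect_true(stock >= 0 && stock <= 50)
    }
  }
})
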