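test_that("empirical choice probabilities satisfy the marginal and layout constraints", {
  # both always own, balanced layouts
  s <- make_own_own_session(200)
  cp <- choice_probs(s)
  for (ag in c("A", "B")) {
    expect_equal(cp$P[ag, "pref", "left"], 0.5)
    expect_equal(cp$P[ag, "pref", "right"], 0.5)
    expect_equal(sum(cp$P[ag, "nonpref", ]), 0)
  }
  # perfect trial turn-taking, counterbalanced: all eight P values 0.25
  cp2 <- choice_probs(make_turn_taking_session(200))
  expect_equal(as.vector(cp2$P), rep(0.25, 8))
  # both fixed objective-left
  cp3 <- choice_probs(make_fixed_side_session(200))
  for (ag in c("A", "B")) {
    expect_equal(cp3$P[ag, "pref", "left"], 0.5)
    expect_equal(cp3$P[ag, "nonpref", "left"], 0.5)
    expect_equal(sum(cp3$P[ag, , "right"]), 0)
  }
  # structural identities on an arbitrary random session
  s4 <- simulate_session(strategy_random(0.3), strategy_random(0.8), 234, seed = 8)
  cp4 <- choice_probs(s4)
  for (ag in c("A", "B")) expect_equal(sum(cp4$P[ag, , ]), 1)
  expect_equal(cp4$P["A", "pref", "left"] + cp4$P["A", "nonpref", "right"],
               cp4$q_left)
  expect_equal(cp4$P["B", "nonpref", "left"] + cp4$P["B", "pref", "right"],
               cp4$q_left)
  expect_equal(cp4$q_left + cp4$q_right, 1)
})

test_that("RPR matches its closed-form benchmarks", {
  expect_equal(rpr(probs_from_fractions(0.5, 0.5, 0.5, 0.5)), 2.5)
  # A and B always own: random play still never coordinates
  expect_equal(rpr(choice_probs(make_own_own_session(200))), 2.0)
  # A always own, B always other: coordination on red every trial
  red <- rep(c("L", "R"), 100)
  s <- build_session(red, red, red)  # B joins A's colour
  expect_equal(rpr(choice_probs(s)), 3.5)
  # degenerate layout probabilities are rejected
  p <- probs_from_fractions(0.5, 0.5, 0.5, 0.5)
  p$q_left <- 0; p$q_right <- 1
  expect_error(rpr(p), "Q")
})

test_that("RPR agrees with a stratified-permutation Monte-Carlo oracle", {
  sessions <- list(
    simulate_session(strategy_random(0.7), strategy_random(0.4), 200, seed = 31),
    simulate_session(strategy_fixed_side("left"), strategy_random(0.5), 200, seed = 32),
    make_turn_taking_session(200))
  for (s in sessions) {
    cp <- choice_probs(s)
    closed <- rpr(cp)
    # random play: permute each agent's choices over trials within layout
    # strata, 500 permutations x 200 trials = 1e5 simulated trials
    mc <- mean(vapply(1:500, function(j)
      average_reward(permute_choices(s, seed = j)), numeric(1)))
    expect_equal(mc, closed, tolerance = 0.01 / closed)
  }
})

test_that("DCR hits the analytic anchors and stays in [-1, 1]", {
  expect_equal(dcr(make_turn_taking_session(200))$dcr, 1)
  expect_equal(dcr(make_anticoordination_session(200))$dcr, -1)
  expect_equal(dcr(make_fixed_side_session(200))$dcr, 0)
  set.seed(77)
  for (i in 1:20) {
    s <- simulate_session(strategy_random(runif(1)), strategy_random(runif(1)),
                          100, seed = 100 + i)
    d <- dcr(s)
    expect_gte(d$dcr, -1); expect_lte(d$dcr, 1)
    expect_lte(d$ci_low, d$dcr); expect_gte(d$ci_high, d$dcr)
    expect_equal(d$dcr, d$r_actual - d$rpr)
    expect_equal(d$significant, d$ci_low > 0 || d$ci_high < 0)
  }
})

test_that("independently shuffled sessions have DCR near zero inside their CI", {
  s <- simulate_session(strategy_trial_turn_taking(), strategy_trial_turn_taking(),
                        200, seed = 55)
  covered <- vapply(1:200, function(j) {
    p <- permute_choices(s, seed = j)
    d <- dcr(p)
    d$ci_low <= 0 && 0 <= d$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("strategy classification recovers the simulated ground truth", {
  cfg <- analysis_config(n_surrogates = 300, seed = 4)
  s_tt <- last_n(simulate_session(strategy_trial_turn_taking(),
                                  strategy_trial_turn_taking(), 400, seed = 11), 200)
  expect_equal(classify_strategy(s_tt, cfg)$label, "dynamic_turn_taking")
  s_fs <- last_n(simulate_session(strategy_fixed_side("left"),
                                  strategy_fixed_side("left"), 400, seed = 12), 200)
  expect_equal(classify_strategy(s_fs, cfg)$label, "static_side")
  s_fc <- last_n(simulate_session(strategy_fixed_color("own"),
                                  strategy_fixed_color("other"), 400, seed = 13), 200)
  expect_equal(classify_strategy(s_fc, cfg)$label, "static_color")
  s_oo <- last_n(simulate_session(strategy_fixed_color("own"),
                                  strategy_fixed_color("own"), 400, seed = 14), 200)
  expect_equal(classify_strategy(s_oo, cfg)$label, "uncoordinated")
  expect_error(classify_strategy(last_n(s_oo, 20), cfg), "too short")
})
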