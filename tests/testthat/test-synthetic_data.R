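test_that("canonical strategy pairings reproduce the textbook outcomes", {
  # both on own colour: never coordinated, joint reward 2
  s <- simulate_session(strategy_fixed_color("own"), strategy_fixed_color("own"),
                        200, seed = 1)
  expect_equal(fco(s, "A")$scalar, 1)
  expect_equal(fco(s, "B")$scalar, 1)
  expect_equal(coordination_fraction(s), 0)
  expect_equal(average_reward(s), 2)

  # both on the objective left over 11 balanced blocks: perfect static
  # coordination, each agent's own colour chosen in exactly half the trials
  s <- simulate_session(strategy_fixed_side("left"), strategy_fixed_side("left"),
                        198, seed = 2)
  expect_equal(coordination_fraction(s), 1)
  expect_equal(fco(s, "A")$scalar, 0.5)
  expect_equal(fco(s, "B")$scalar, 0.5)
  expect_equal(fcl(s, "A")$scalar, 1)

  # aligned trial-by-trial turn-taking: perfect dynamic coordination
  s <- simulate_session(strategy_trial_turn_taking(), strategy_trial_turn_taking(),
                        200, seed = 3)
  expect_equal(coordination_fraction(s), 1)
  expect_equal(average_reward(s), 3.5)
})

test_that("sessions are deterministic given the seed and satisfy invariants", {
  s1 <- simulate_session(strategy_random(), strategy_random(0.7), 100, seed = 42)
  s2 <- simulate_session(strategy_random(), strategy_random(0.7), 100, seed = 42)
  expect_identical(s1$trials, s2$trials)
  expect_silent(validate_session(s1))
  s3 <- simulate_session(strategy_random(), strategy_random(0.7), 100, seed = 43)
  expect_false(identical(s1$trials, s3$trials))
})

test_that("confederate schedule alternates colours in blocks", {
  plan <- confederate_schedule(60, block_len = 20, seed = 1, first_color = "red")
  expect_equal(plan, rep(c("red", "blue", "red"), each = 20))
  plan40 <- confederate_schedule(40, block_len = 20, seed = 1, first_color = "blue")
  expect_equal(unique(plan40[1:20]), "blue")
  expect_equal(unique(plan40[21:40]), "red")
  jit <- confederate_schedule(200, block_len = 20, jitter = 3, seed = 5)
  runs <- rle(jit)$lengths
  expect_true(all(head(runs, -1) >= 17 & head(runs, -1) <= 23))
  expect_error(confederate_schedule(10, block_len = 0), "block_len")
})

test_that("a perfect follower tracks a faster confederate's plan trialwise", {
  fast <- action_time_model(mean_action_ms = 250, sd_action_ms = 20)
  slow <- action_time_model(mean_action_ms = 900, sd_action_ms = 20)
  s <- simulate_session(strategy_confederate(block_len = 20, first_color = "red"),
                        strategy_leader_follower(strategy_fixed_color("own"), 1),
                        300, at_a = fast, at_b = slow, seed = 11)
  plan <- s$meta$plan_A
  followed <- s$meta$followed_B
  expect_gt(mean(followed), 0.99)
  expect_true(all(color_series(s, "B")[followed] == plan[followed]))
  # realised follower action times lag the leader
  at <- session_action_times(s)
  expect_true(all(at$at_B[followed] >= at$at_A[followed] + 149))
})

test_that("an opaque barrier abolishes following", {
  fast <- action_time_model(mean_action_ms = 250, sd_action_ms = 20)
  slow <- action_time_model(mean_action_ms = 900, sd_action_ms = 20)
  vis <- opaque_window(300, 101, 200)
  s <- simulate_session(strategy_confederate(block_len = 20, first_color = "red"),
                        strategy_leader_follower(strategy_fixed_color("own"), 1),
                        300, at_a = fast, at_b = slow, visible = vis, seed = 12)
  expect_equal(sum(s$meta$followed_B[101:200]), 0L)
  expect_gt(mean(s$meta$followed_B[c(1:100, 201:300)]), 0.99)
  # with the barrier, the follower's colour choices carry no information
  # about the confederate's plan
  s_op <- simulate_session(strategy_confederate(block_len = 20, first_color = "red"),
                           strategy_leader_follower(strategy_fixed_color("own"), 1),
                           400, at_a = fast, at_b = slow, visible = FALSE,
                           seed = 13)
  mi <- mi_significance(color_series(s_op, "B"), s_op$meta$plan_A,
                        n_surrogates = 300, seed = 2)
  expect_false(mi$significant)
})

test_that("following rate approaches one for a fidelity-1 slower follower", {
  fast <- action_time_model(mean_action_ms = 250, sd_action_ms = 20)
  slow <- action_time_model(mean_action_ms = 900, sd_action_ms = 20)
  s <- simulate_session(strategy_fixed_color("own"),
                        strategy_leader_follower(strategy_fixed_color("own"), 1),
                        400, at_a = fast, at_b = slow, seed = 14)
  expect_gt(mean(s$meta$followed_B), 0.99)
  expect_gt(coordination_fraction(s), 0.99)
})

test_that("simulated timestamps are positive, ordered and integer-valued", {
  s <- simulate_session(strategy_random(), strategy_random(), 150, seed = 21)
  tr <- s$trials
  for (ag in c("A", "B")) {
    rel <- tr[[paste0("t_rel_", ag, "_ms")]]
    acq <- tr[[paste0("t_acq_", ag, "_ms")]]
    expect_true(all(rel > 0))
    expect_true(all(acq > rel))
    expect_equal(rel, round(rel))
  }
})
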