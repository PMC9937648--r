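test_that("action time is the halfway point of the reach", {
  expect_equal(action_time(200, 400)$t_movement, 200)
  expect_equal(action_time(200, 400)$t_action, 300)
  expect_equal(action_time(0, 0)$t_action, 0)
  at <- action_time(250, 564)
  expect_equal(at$t_movement, 314)
  expect_equal(at$t_action, 407)
  expect_error(action_time(400, 200), "t_release after")
  expect_true(is.na(action_time(NA, 300)$t_action))
})

test_that("Welch tests equal the closed-form oracle to 1e-10", {
  set.seed(12)
  for (i in 1:20) {
    g1 <- rnorm(sample(5:40, 1), mean = runif(1, 80, 120), sd = runif(1, 5, 60))
    g2 <- rnorm(sample(5:40, 1), mean = runif(1, 80, 120), sd = runif(1, 5, 60))
    got <- bosgame:::welch_result("x", g1, g2)
    want <- oracle_welch(g1, g2)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # the textbook worked case: N = 30 each, means 100 vs 200, SDs 50 vs 100
  g1 <- scale(rnorm(30))[, 1] * 50 + 100
  g2 <- scale(rnorm(30))[, 1] * 100 + 200
  got <- bosgame:::welch_result("x", g1, g2)
  expect_equal(got$t, -4.8990, tolerance = 1e-3)
  expect_equal(got$df, 42.6470, tolerance = 1e-3)
  # identical groups
  same <- bosgame:::welch_result("x", c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("the three AT-difference tests expose leader-follower structure", {
  # confederate A alternates colour blocks; B follows to A's red but plays
  # his own blue at baseline (the confederate-training configuration)
  fast <- action_time_model(mean_action_ms = 450, sd_action_ms = 120)
  slow <- action_time_model(mean_action_ms = 550, sd_action_ms = 120)
  s <- simulate_session(strategy_confederate(block_len = 20, first_color = "red"),
                        strategy_leader_follower(strategy_fixed_color("own"), 1),
                        500, at_a = fast, at_b = slow, seed = 61)
  res <- at_tests(s)
  expect_true(all(vapply(res, function(r) r$computable, logical(1))))
  # A is faster overall
  expect_lt(res$at_A_vs_B$t, 0)
  expect_lt(res$at_A_vs_B$p, 0.001)
  # AT_A - AT_B is more negative in trials coordinated on A's colour
  # (B waited for A before accommodating) than on B's colour
  expect_lt(res$atdiff_coordA_vs_coordB$t, 0)
  expect_lt(res$atdiff_coordA_vs_coordB$mean1,
            res$atdiff_coordA_vs_coordB$mean2)
  # waiting happens during coordination: larger absolute AT differences in
  # coordinated than uncoordinated trials
  expect_gt(res$absdiff_coord_vs_uncoord$t, 0)
  # missing timestamps make the tests not computable
  s_nt <- make_turn_taking_session(100)
  expect_false(at_tests(s_nt)$at_A_vs_B$computable)
})

test_that("psee matches its defining values and logistic symmetry", {
  expect_equal(psee(50), 0.5)
  expect_equal(round(psee(150), 2), 0.98)
  expect_equal(psee(-1e6), 0, tolerance = 1e-12)
  expect_equal(psee(1e6), 1)
  # psee(dt0) = 0.5 for any slope; monotone; symmetric about (dt0, 0.5)
  for (k in c(0.01, 0.04, 0.16)) {
    expect_equal(psee(50, k = k), 0.5)
    dts <- seq(-150, 250, by = 10)  # away from double-precision saturation
    expect_true(all(diff(psee(dts, k = k)) > 0))
    a <- seq(-200, 200, by = 25)
    expect_equal(psee(a, k = k) + psee(100 - a, k = k), rep(1, length(a)))
  }
})

test_that("visibility correlation tracks following and flags degeneracies", {
  at <- action_time_model(mean_action_ms = 500, sd_action_ms = 120)
  s <- simulate_session(strategy_fixed_color("own"),
                        strategy_leader_follower(strategy_fixed_color("own"), 1),
                        400, at_a = at, at_b = at, seed = 7)
  vc <- visibility_correlation(s)
  expect_gt(vc$B$r_raw, 0.5)
  expect_gt(vc$B$r_smoothed, 0.5)
  expect_lt(vc$B$p_raw, 0.001)
  expect_lt(vc$B$p_smoothed, 0.001)
  # fidelity 0: following is unrelated to visibility
  s0 <- simulate_session(strategy_fixed_color("own"),
                         strategy_leader_follower(strategy_random(0.5), 0),
                         400, at_a = at, at_b = at, seed = 8)
  vc0 <- visibility_correlation(s0, n_perm = 500, seed = 3)
  expect_gt(vc0$B$p_raw_shuffle, 0.01)
  # identical action times every trial -> psee constant -> undefined
  s_const <- with_timestamps(make_turn_taking_session(100), 300, 300)
  vcc <- visibility_correlation(s_const)
  expect_true(vcc$A$undefined)
  expect_true(vcc$B$undefined)
})

test_that("the psee parameter sweep covers 11 settings and degrades only at dt0 = 200", {
  at <- action_time_model(mean_action_ms = 500, sd_action_ms = 120)
  s <- simulate_session(strategy_fixed_color("own"),
                        strategy_leader_follower(strategy_random(0.5), 1),
                        500, at_a = at, at_b = at, seed = 9)
  tab <- psee_robustness(s)
  expect_equal(nrow(tab), 11L)
  expect_equal(sum(tab$k == 0.04 & tab$dt0 == 50), 2L)  # shared default point
  dt0_rows <- tab[seq_len(6), ]
  expect_equal(which.min(dt0_rows$r_raw_B), 6L)  # dt0 = 200 drops most
  expect_true(all(dt0_rows$r_raw_B[-6] > 0.4))
  # degenerate session: every entry undefined
  tab2 <- psee_robustness(with_timestamps(make_turn_taking_session(100), 300, 300))
  expect_true(all(tab2$undefined))
  expect_true(all(is.na(tab2$r_raw_A)))
})
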