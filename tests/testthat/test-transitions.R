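test_that("coordination segmentation partitions the session by mode", {
  # block turn-taking in blocks of 20 -> alternating coordination segments
  s <- simulate_session(strategy_block_turn_taking(20),
                        strategy_block_turn_taking(20), 100, seed = 1)
  seg <- segment_coordination(s)
  expect_equal(nrow(seg), 5L)
  expect_equal(seg$length, rep(20L, 5))
  expect_equal(seg$mode, rep(c("coord_on_A_color", "coord_on_B_color"),
                             length.out = 5))
  # all own-own: a single segment
  seg2 <- segment_coordination(make_own_own_session(50))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$mode, "own_own")
  # one uncoordinated trial between two coordination colours -> 3 segments
  red <- rep("L", 9)
  side_a <- c("L", "L", "L", "L", "L", "R", "R", "R", "R")
  side_b <- c("L", "L", "L", "L", "R", "R", "R", "R", "R")  # trial 5 own-own
  s3 <- build_session(red, side_a, side_b)
  seg3 <- segment_coordination(s3)
  expect_equal(seg3$mode, c("coord_on_A_color", "own_own", "coord_on_B_color"))
  # segments partition the session, consecutive modes differ
  s4 <- simulate_session(strategy_random(), strategy_random(), 300, seed = 2)
  seg4 <- segment_coordination(s4)
  expect_equal(sum(seg4$length), 300L)
  expect_equal(seg4$start[-1L], seg4$end[-nrow(seg4)] + 1L)
  expect_true(all(seg4$mode[-1L] != seg4$mode[-nrow(seg4)]))
})

test_that("seamless switches are counted per boundary and attributed to the faster agent", {
  # trial-by-trial turn-taking with A always faster: every trial pair is a
  # seamless switch, and A's choice alternates own/other -> balanced
  s <- with_timestamps(make_turn_taking_session(100), rel_a = 300, rel_b = 500)
  sw <- seamless_switches(s)
  expect_equal(sw$n_switches, 99L)
  expect_equal(sw$n_unattributed, 0L)
  expect_equal(sw$n_selfish + sw$n_benevolent, 99L)
  expect_lte(abs(sw$n_selfish - sw$n_benevolent), 1L)
  expect_equal(sw$verdict, "balanced")
  expect_equal(sw$n_switches,
               sw$n_selfish + sw$n_benevolent + sw$n_unattributed)
  # non-coordination gaps at every colour change -> zero seamless switches
  red <- rep("L", 12)
  side_a <- c("L", "L", "L", "L", "L", "R", "R", "R", "R", "R", "R", "R")
  side_b <- c("L", "L", "L", "L", "R", "R", "R", "R", "R", "R", "R", "R")
  s2 <- build_session(red, side_a, side_b)
  expect_equal(seamless_switches(s2)$n_switches, 0L)
  # removing the gap trial makes the colour change seamless again
  s2b <- build_session(red[1:10], side_a[c(1:4, 6:11)], side_b[c(1:4, 6:11)])
  expect_equal(seamless_switches(s2b)$n_switches, 1L)
  # fixed-side pair: a seamless switch at every layout side flip
  s3 <- make_fixed_side_session(100)
  flips <- sum(s3$trials$red_side[-1L] != s3$trials$red_side[-100])
  expect_equal(seamless_switches(s3)$n_switches, flips)
  # ties in action time stay unattributed
  s4 <- with_timestamps(make_turn_taking_session(20), 300, 300)
  sw4 <- seamless_switches(s4)
  expect_equal(sw4$n_unattributed, sw4$n_switches)
  expect_equal(sw4$verdict, "not_applicable")
})

test_that("uncoordinated trial classes get exact binomial verdicts", {
  # equal own-own and other-other counts
  red <- rep("L", 80)
  own_own <- rep(c(TRUE, FALSE), 40)
  s <- build_session(red, ifelse(own_own, "L", "R"), ifelse(own_own, "R", "L"))
  u <- uncoordinated_classes(s)
  expect_equal(u$n_own_own, 40L)
  expect_equal(u$n_other_other, 40L)
  expect_equal(u$verdict, "balanced")
  # 95 own-own vs 5 other-other: selfish (binomial CI excludes 0.5)
  own_own2 <- c(rep(TRUE, 95), rep(FALSE, 5))
  s2 <- build_session(rep("L", 100), ifelse(own_own2, "L", "R"),
                      ifelse(own_own2, "R", "L"))
  u2 <- uncoordinated_classes(s2)
  ci <- binom.test(5, 100)$conf.int
  expect_equal(u2$ci_low, ci[1])
  expect_equal(u2$ci_high, ci[2])
  expect_lt(u2$ci_high, 0.5)
  expect_equal(u2$verdict, "selfish")
  # all coordinated -> not applicable
  expect_equal(uncoordinated_classes(make_turn_taking_session(40))$verdict,
               "not_applicable")
})

test_that("transition-aligned AT profiles recover injected timing effects", {
  # stationary session with constant ATs: profile flat at the constants
  red <- rep("L", 60)
  side_a <- rep(c("L", "L", "L", "L", "L", "R"), 10)  # own-own every 6th
  s <- build_session(red, side_a, rep("L", 60))
  s <- with_timestamps(s, 300, 400)
  prof <- transition_at_profile(s)
  expect_true(all(prof$at_A == 400))  # 300 release + 200/2 movement
  expect_true(all(prof$at_B == 500))
  expect_setequal(unique(prof$type), c("to_coordination", "from_coordination"))
  # inject a 100 ms speed-up of agent A at non-coordination onsets
  rel_a <- rep(300, 60)
  trans_trials <- which(side_a == "R")
  rel_a[trans_trials] <- 200
  s2 <- with_timestamps(build_session(red, side_a, rep("L", 60)), 300, 400)
  s2$trials$t_rel_A_ms <- rel_a
  s2$trials$t_acq_A_ms <- rel_a + 200
  prof2 <- transition_at_profile(s2)
  from <- prof2[prof2$type == "from_coordination", ]
  expect_equal(from$at_A[from$offset == 0], 300)   # 100 ms faster
  expect_equal(from$at_A[from$offset == -1], 400)
  # no transitions -> empty profile
  expect_equal(nrow(transition_at_profile(make_own_own_session(30))), 0L)
})
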