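# Session builders used across the suite. All are deterministic
# constructions with exactly counterbalanced layouts, so the analytic
# worked-example values (DCR = +1 / -1 / 0, MI = 1, joint reward 3.5) hold
# exactly rather than approximately.

opposite <- function(s) ifelse(s == "L", "R", "L")

build_session <- function(red_side, side_a, side_b, visible = 1L,
                          t_rel_a = NA_real_, t_acq_a = NA_real_,
                          t_rel_b = NA_real_, t_acq_b = NA_real_, ...) {
  ev <- evaluate_trial(red_side, side_a, side_b)
  n <- length(red_side)
  bos_session(data.frame(
    trial = seq_len(n), red_side = red_side,
    side_A = ev$side_A, side_B = ev$side_B,
    choice_A = ev$choice_A, choice_B = ev$choice_B,
    reward_A = ev$reward_A, reward_B = ev$reward_B,
    t_rel_A_ms = t_rel_a, t_acq_A_ms = t_acq_a,
    t_rel_B_ms = t_rel_b, t_acq_B_ms = t_acq_b,
    visible = visible, stringsAsFactors = FALSE), ...)
}

# Strict trial-by-trial turn-taking with sides exactly counterbalanced
# within each coordination mode: 4-trial cycle (A-colour on L, B-colour on
# L, A-colour on R, B-colour on R). n must be a multiple of 4.
make_turn_taking_session <- function(n = 200L, ...) {
  stopifnot(n %% 4L == 0L)
  red <- rep(c("L", "L", "R", "R"), n / 4L)
  on_a <- rep(c(TRUE, FALSE), n / 2L)
  side <- ifelse(on_a, red, opposite(red))  # both agents on the same target
  build_session(red, side, side, ...)
}

# Alternation between the own-own and other-other uncoordinated outcomes,
# sides counterbalanced. n must be a multiple of 4.
make_anticoordination_session <- function(n = 200L, ...) {
  stopifnot(n %% 4L == 0L)
  red <- rep(c("L", "L", "R", "R"), n / 4L)
  own_own <- rep(c(TRUE, FALSE), n / 2L)
  side_a <- ifelse(own_own, red, opposite(red))
  side_b <- ifelse(own_own, opposite(red), red)
  build_session(red, side_a, side_b, ...)
}

# Both agents statically on one objective side, red side exactly balanced.
make_fixed_side_session <- function(n = 200L, side = "L", ...) {
  stopifnot(n %% 2L == 0L)
  red <- rep(c("L", "R"), n / 2L)
  build_session(red, rep(side, n), rep(side, n), ...)
}

# Both agents always on their own preferred colour (never coordinated).
make_own_own_session <- function(n = 200L, ...) {
  stopifnot(n %% 2L == 0L)
  red <- rep(c("L", "R"), n / 2L)
  build_session(red, red, opposite(red), ...)
}

# Attach constant-offset timestamps: agent A releases at rel_a and moves
# mov ms, agent B at rel_b (vectors recycled to n).
with_timestamps <- function(session, rel_a, rel_b, mov = 200) {
  tr <- session$trials
  n <- nrow(tr)
  tr$t_rel_A_ms <- rep_len(rel_a, n)
  tr$t_acq_A_ms <- rep_len(rel_a + mov, n)
  tr$t_rel_B_ms <- rep_len(rel_b, n)
  tr$t_acq_B_ms <- rep_len(rel_b + mov, n)
  bos_session(tr, agents = session$agents, species = session$species,
              condition = session$condition, meta = session$meta)
}

tmp_file <- function(name) file.path(tempdir(), name)
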