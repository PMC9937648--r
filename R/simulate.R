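# Agent-based simulation of dyadic transparent BoS sessions.

#' Action-time model for a simulated agent
#'
#' Action times (the halfway point of the reach, measured from the go
#' signal) and movement times are drawn from independent truncated normal
#' distributions; the truncation floor keeps all sampled times strictly
#' positive and the release time (`t_action - t_movement / 2`) positive.
#'
#' The default movement parameters follow typical human reach movements in
#' touch-screen dyadic tasks (roughly 314 +/- 104 ms); the action-time mean
#' adds a plausible reaction-time component.
#'
#' @param mean_action_ms,sd_action_ms mean and SD of the action time (ms).
#' @param mean_movement_ms,sd_movement_ms mean and SD of the movement time.
#' @param floor_ms truncation floor (ms, default 50).
#' @return An object of class `bos_at_model`.
#' @export
action_time_model <- function(mean_action_ms = 600, sd_action_ms = 120,
                              mean_movement_ms = 314, sd_movement_ms = 104,
                              floor_ms = 50) {
  stopifnot(mean_action_ms > 0, sd_action_ms > 0,
            mean_movement_ms > 0, sd_movement_ms > 0, floor_ms > 0)
  structure(list(mean_action_ms = mean_action_ms, sd_action_ms = sd_action_ms,
                 mean_movement_ms = mean_movement_ms,
                 sd_movement_ms = sd_movement_ms, floor_ms = floor_ms),
            class = "bos_at_model")
}

# One draw from N(mean, sd) truncated below at `lower` (inverse-CDF, exact).
rtnorm1 <- function(mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(1) * (1 - p0), mean, sd)
}

#' Opaque-segment visibility schedule
#'
#' @param n_trials session length.
#' @param from,to first and last trial of the opaque segment (inclusive).
#' @return Logical vector: `TRUE` where the display is transparent.
#' @export
opaque_window <- function(n_trials, from, to) {
  stopifnot(from >= 1, to <= n_trials, from <= to)
  visible <- rep(TRUE, n_trials)
  visible[from:to] <- FALSE
  visible
}

#' Simulate a dyadic BoS session
#'
#' Plays `n_trials` of the transparent BoS game between two parametrised
#' agents (see [strategies]) with per-agent action-time models, and returns
#' a fully populated [bos_session()].
#'
#' Within each trial the simulator (consuming a single RNG stream in this
#' documented order):
#' \enumerate{
#'   \item draws agent A's movement and action time, then agent B's, from
#'     the truncated normal models;
#'   \item computes the baseline colour choice of A, then of B (the
#'     `random` strategy consumes one uniform draw here);
#'   \item determines the faster agent from the provisional action times
#'     (exact ties are broken by a coin flip);
#'   \item if the slower agent plays a `leader_follower` strategy and the
#'     trial is transparent, draws one uniform variate and, with
#'     probability `psee(dt) * follow_fidelity` where
#'     `dt = AT_slower - AT_faster`, replaces the slower agent's choice by
#'     the faster agent's physical target; a follower that copies waits for
#'     the leader, so its realised action time becomes
#'     `max(own draw, leader's action time + follow_lag_ms)`.
#' }
#' The layout schedule is generated first (balanced sets of 18 trials), and
#' confederate plans are drawn before the trial loop. Realised timestamps
#' are rounded to integer milliseconds so that sessions survive a TSV
#' round trip bit-exactly.
#'
#' @param strategy_a,strategy_b `bos_strategy` objects for agents A and B.
#' @param n_trials number of trials (>= 1).
#' @param at_a,at_b `bos_at_model` action-time models.
#' @param visible logical scalar or length-`n_trials` vector; `FALSE`
#'   marks opaque trials in which actions cannot be seen (see
#'   [opaque_window()]).
#' @param psee_k,psee_dt0 parameters of the logistic visibility model
#'   passed to [psee()] (defaults 0.04 per ms and 50 ms).
#' @param follow_lag_ms reaction lag added to the leader's action time when
#'   a follower copies (default 150 ms).
#' @param seed integer seed; the session is deterministic given the seed.
#' @param species,agents metadata stored in the session.
#' @return A `bos_session`. The metadata records the effective simulator
#'   parameters, any confederate plans (`meta$plan_A`, `meta$plan_B`), and
#'   per-trial follow indicators (`meta$followed_A/B`, `TRUE` where the
#'   agent copied the partner's target).
#' @export
simulate_session <- function(strategy_a, strategy_b, n_trials,
                             at_a = action_time_model(),
                             at_b = action_time_model(),
                             visible = TRUE,
                             psee_k = 0.04, psee_dt0 = 50,
                             follow_lag_ms = 150, seed = 1L,
                             species = "synthetic", agents = c("A", "B")) {
  stopifnot(inherits(strategy_a, "bos_strategy"),
            inherits(strategy_b, "bos_strategy"),
            inherits(at_a, "bos_at_model"), inherits(at_b, "bos_at_model"),
            n_trials >= 1)
  n_trials <- as.integer(n_trials)
  if (length(visible) == 1L) visible <- rep(visible, n_trials)
  stopifnot(length(visible) == n_trials)
  visible <- as.logical(visible)

  local_seed(seed)
  n_blocks <- ceiling(n_trials / 18L)
  red_pos <- unlist(lapply(seq_len(n_blocks), function(b) sample(rep(1:6, 3L))))
  red_pos <- red_pos[seq_len(n_trials)]
  red_side <- ifelse(red_pos <= 3L, "L", "R")

  plans <- list(A = NULL, B = NULL)
  for (role in c("A", "B")) {
    s <- if (role == "A") strategy_a else strategy_b
    conf <- if (s$kind == "confederate") s
            else if (s$kind == "leader_follower" &&
                     s$baseline$kind == "confederate") s$baseline
            else NULL
    if (!is.null(conf))
      plans[[role]] <- confederate_plan(n_trials, conf$block_len,
                                        conf$jitter, conf$first_color)
  }

  side_A <- side_B <- character(n_trials)
  t_act <- matrix(NA_real_, n_trials, 2L, dimnames = list(NULL, c("A", "B")))
  t_mov <- t_act
  followed <- matrix(FALSE, n_trials, 2L, dimnames = list(NULL, c("A", "B")))
  strategies <- list(A = strategy_a, B = strategy_b)
  models <- list(A = at_a, B = at_b)

  for (t in seq_len(n_trials)) {
    mov <- act <- c(A = NA_real_, B = NA_real_)
    for (role in c("A", "B")) {
      m <- models[[role]]
      mov[role] <- rtnorm1(m$mean_movement_ms, m$sd_movement_ms, m$floor_ms)
      act[role] <- rtnorm1(m$mean_action_ms, m$sd_action_ms,
                           m$floor_ms + mov[role] / 2)
    }
    choice <- c(A = baseline_choice(strategy_a, "A", t, red_side[t], plans$A),
                B = baseline_choice(strategy_b, "B", t, red_side[t], plans$B))
    side <- c(A = choice_to_side(choice["A"], "A", red_side[t]),
              B = choice_to_side(choice["B"], "B", red_side[t]))
    faster <- if (act["A"] < act["B"]) "A"
              else if (act["B"] < act["A"]) "B"
              else sample(c("A", "B"), 1L)
    slower <- setdiff(c("A", "B"), faster)
    s_slow <- strategies[[slower]]
    if (s_slow$kind == "leader_follower" && visible[t]) {
      p_follow <- psee(act[slower] - act[faster], psee_k, psee_dt0) *
        s_slow$follow_fidelity
      if (stats::runif(1) < p_follow) {
        side[slower] <- side[faster]
        act[slower] <- max(act[slower], act[faster] + follow_lag_ms)
        followed[t, slower] <- TRUE
      }
    }
    side_A[t] <- side["A"]; side_B[t] <- side["B"]
    t_act[t, ] <- act[c("A", "B")]
    t_mov[t, ] <- mov[c("A", "B")]
  }

  outcome <- evaluate_trial(red_side, side_A, side_B)
  trials <- data.frame(
    trial = seq_len(n_trials), red_side = red_side, red_pos = red_pos,
    side_A = side_A, side_B = side_B,
    choice_A = outcome$choice_A, choice_B = outcome$choice_B,
    reward_A = outcome$reward_A, reward_B = outcome$reward_B,
    t_rel_A_ms = round(t_act[, "A"] - t_mov[, "A"] / 2),
    t_acq_A_ms = round(t_act[, "A"] + t_mov[, "A"] / 2),
    t_rel_B_ms = round(t_act[, "B"] - t_mov[, "B"] / 2),
    t_acq_B_ms = round(t_act[, "B"] + t_mov[, "B"] / 2),
    visible = as.integer(visible), stringsAsFactors = FALSE)

  bos_session(trials, agents = agents, species = species,
              condition = if (any(vapply(plans, Negate(is.null), TRUE)))
                "confederate" else "dyadic",
              meta = list(seed = seed, psee_k = psee_k, psee_dt0 = psee_dt0,
                          follow_lag_ms = follow_lag_ms,
                          strategy_A = strategy_a$kind,
                          strategy_B = strategy_b$kind,
                          plan_A = plans$A, plan_B = plans$B,
                          followed_A = followed[, "A"],
                          followed_B = followed[, "B"]))
}

#' Random-play permutation of a session
#'
#' Builds the "playing randomly" counterpart of a session: each agent's
#' colour choices are permuted independently over trials within layout
#' strata (red-on-left and red-on-right trials separately), which preserves
#' each agent's side-conditional choice probabilities while destroying any
#' trial-by-trial dependence between the agents. Rewards and sides are
#' re-derived from the permuted choices. Timestamps are dropped.
#'
#' @param session a `bos_session`.
#' @param seed integer seed for the permutation.
#' @return A permuted `bos_session`.
#' @export
permute_choices <- function(session, seed = 1L) {
  tr <- session$trials
  local_seed(seed)
  ch_a <- tr$choice_A
  ch_b <- tr$choice_B
  for (s in c("L", "R")) {
    idx <- which(tr$red_side == s)
    if (length(idx) > 1L) {
      ch_a[idx] <- ch_a[sample(idx)]
      ch_b[idx] <- ch_b[sample(idx)]
    }
  }
  side_a <- vapply(seq_len(nrow(tr)), function(i)
    choice_to_side(ch_a[i], "A", tr$red_side[i]), character(1))
  side_b <- vapply(seq_len(nrow(tr)), function(i)
    choice_to_side(ch_b[i], "B", tr$red_side[i]), character(1))
  outcome <- evaluate_trial(tr$red_side, side_a, side_b)
  trials <- data.frame(
    trial = tr$trial, red_side = tr$red_side, red_pos = tr$red_pos,
    side_A = side_a, side_B = side_b,
    choice_A = outcome$choice_A, choice_B = outcome$choice_B,
    reward_A = outcome$reward_A, reward_B = outcome$reward_B,
    visible = tr$visible, stringsAsFactors = FALSE)
  bos_session(trials, agents = session$agents, species = session$species,
              condition = session$condition,
              meta = c(session$meta, list(permuted = TRUE)))
}
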