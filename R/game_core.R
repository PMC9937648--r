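# Payoff structure, layout randomisation and trial evaluation for the
# transparent Bach-or-Stravinsky (BoS) game.
#
# Conventions used throughout the package:
#   * Agent A's individually preferred colour is "red", agent B's is "blue".
#   * All sides are OBJECTIVE, i.e. expressed in agent A's frame. The two
#     agents face each other, so the same objective side always denotes the
#     same physical target for both.
#   * A choice is "own" when the agent selects its individually preferred
#     colour, "other" when it selects the partner's preferred colour.

#' BoS payoff for one trial
#'
#' Reward schedule of the Bach-or-Stravinsky game: selecting the own
#' preferred colour is worth 2 base units, selecting the partner's preferred
#' colour 1 base unit, and when both agents land on the same physical target
#' a coordination bonus of 2 units is added for each. The four possible
#' choice combinations therefore pay (own, own) = (2, 2), (other, other) =
#' (1, 1), (own, other) = (4, 3) and (other, own) = (3, 4): the two agents
#' coordinate exactly when one picks "own" and the other "other", because
#' they then reach for the same colour.
#'
#' @param choice_a,choice_b character vectors with elements `"own"` or
#'   `"other"`, the colour-category choices of agents A and B.
#' @return A data.frame with integer columns `reward_a`, `reward_b` and a
#'   logical column `coordinated`.
#' @examples
#' bos_payoff("own", "other")   # coordinated on A's colour: 4 and 3
#' bos_payoff("own", "own")     # uncoordinated: 2 and 2
#' @export
bos_payoff <- function(choice_a, choice_b) {
  stopifnot(all(choice_a %in% c("own", "other")),
            all(choice_b %in% c("own", "other")),
            length(choice_a) == length(choice_b))
  coordinated <- choice_a != choice_b
  base_a <- ifelse(choice_a == "own", 2L, 1L)
  base_b <- ifelse(choice_b == "own", 2L, 1L)
  data.frame(reward_a = base_a + 2L * coordinated,
             reward_b = base_b + 2L * coordinated,
             coordinated = coordinated)
}

#' Balanced target-layout schedule
#'
#' Randomises the position of agent A's preferred ("red") target over the
#' six possible positions (3 heights x 2 sides), balanced in consecutive
#' sets of 18 trials so that each position occurs exactly three times per
#' set; the partner target always occupies the vertically mirrored position
#' on the opposite side. A session length that is not a multiple of 18 is
#' completed by truncating one extra freshly shuffled balanced set.
#'
#' Positions 1-3 are on the objective left, 4-6 on the objective right, so
#' over any whole number of balanced sets the red target appears on each
#' side exactly half of the time.
#'
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return A data.frame with columns `trial`, `red_pos` (1-6) and
#'   `red_side` (`"L"`/`"R"`, objective side of the red target).
#' @export
make_layout_schedule <- function(n_trials, seed = 1L) {
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1)
    stop("'n_trials' must be a positive count")
  n_trials <- as.integer(n_trials)
  local_seed(seed)
  n_blocks <- ceiling(n_trials / 18L)
  pos <- unlist(lapply(seq_len(n_blocks), function(b) sample(rep(1:6, 3L))))
  pos <- pos[seq_len(n_trials)]
  data.frame(trial = seq_len(n_trials),
             red_pos = pos,
             red_side = ifelse(pos <= 3L, "L", "R"),
             stringsAsFactors = FALSE)
}

#' Evaluate trials from objective side choices
#'
#' Maps each agent's objective side choice onto its colour-category choice
#' under the given layout, determines coordination (same objective side =
#' same physical target) and fills in the payoff.
#'
#' @param red_side character vector, objective side of agent A's preferred
#'   colour per trial (`"L"`/`"R"`).
#' @param side_a,side_b objective side selected by agents A and B.
#' @return data.frame with columns `red_side`, `side_A`, `side_B`,
#'   `choice_A`, `choice_B`, `coordinated`, `reward_A`, `reward_B`.
#' @export
evaluate_trial <- function(red_side, side_a, side_b) {
  n <- length(red_side)
  stopifnot(length(side_a) == n, length(side_b) == n,
            all(red_side %in% c("L", "R")),
            all(side_a %in% c("L", "R")), all(side_b %in% c("L", "R")))
  blue_side <- ifelse(red_side == "L", "R", "L")
  choice_a <- ifelse(side_a == red_side, "own", "other")
  choice_b <- ifelse(side_b == blue_side, "own", "other")
  pay <- bos_payoff(choice_a, choice_b)
  data.frame(red_side = red_side, side_A = side_a, side_B = side_b,
             choice_A = choice_a, choice_B = choice_b,
             coordinated = pay$coordinated,
             reward_A = pay$reward_a, reward_B = pay$reward_b,
             stringsAsFactors = FALSE)
}

#' Construct a dyadic session object
#'
#' A `bos_session` bundles an ordered per-trial table with pair metadata.
#' The trial table uses the columns of the session TSV dialect (see
#' [write_session()]); timestamp columns may be `NA` when action times were
#' not recorded.
#'
#' @param trials data.frame of per-trial records. Required columns:
#'   `trial`, `red_side`, `red_pos`, `side_A`, `side_B`, `choice_A`,
#'   `choice_B`, `reward_A`, `reward_B`, `t_rel_A_ms`, `t_acq_A_ms`,
#'   `t_rel_B_ms`, `t_acq_B_ms`, `visible`. Missing optional columns are
#'   completed (`red_pos` from side, timestamps as `NA`, `visible` as 1).
#' @param agents character vector of length 2 with the agent labels.
#' @param species free-form species/pair tag (e.g. `"human"`,
#'   `"macaque"`, `"synthetic"`).
#' @param condition condition label (`"dyadic"`, `"confederate"`, `"solo"`).
#' @param meta optional list of extra metadata (e.g. simulator parameters).
#' @param validate check the trial-table invariants (default `TRUE`).
#' @return An object of class `bos_session`.
#' @export
bos_session <- function(trials, agents = c("A", "B"), species = "unknown",
                        condition = "dyadic", meta = list(), validate = TRUE) {
  stopifnot(is.data.frame(trials), length(agents) == 2L)
  if (is.null(trials$trial)) trials$trial <- seq_len(nrow(trials))
  if (is.null(trials$red_pos))
    trials$red_pos <- ifelse(trials$red_side == "L", 1L, 4L)
  for (col in c("t_rel_A_ms", "t_acq_A_ms", "t_rel_B_ms", "t_acq_B_ms"))
    if (is.null(trials[[col]])) trials[[col]] <- NA_real_
  if (is.null(trials$visible)) trials$visible <- 1L
  cols <- c("trial", "red_side", "red_pos", "side_A", "side_B", "choice_A",
            "choice_B", "reward_A", "reward_B", "t_rel_A_ms", "t_acq_A_ms",
            "t_rel_B_ms", "t_acq_B_ms", "visible")
  missing <- setdiff(cols, names(trials))
  if (length(missing))
    stop("trial table lacks required columns: ", paste(missing, collapse = ", "))
  session <- structure(list(trials = trials[, cols], agents = agents,
                            species = species, condition = condition,
                            meta = meta),
                       class = "bos_session")
  if (validate) validate_session(session)
  session
}

#' Number of trials in a session
#' @param session a `bos_session`.
#' @export
n_trials <- function(session) nrow(session$trials)

#' Validate the internal consistency of a session
#'
#' Checks the per-trial invariants: strictly increasing trial indices,
#' colour choices consistent with the layout and the chosen sides, rewards
#' consistent with the payoff matrix (joint sums restricted to 7, 4 and 2),
#' and release preceding acquisition whenever both timestamps are present.
#' Violations raise an error naming the first offending row.
#'
#' @param session a `bos_session`.
#' @return The session, invisibly.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  fail <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      stop(sprintf("invalid session: %s (first offending row %d)",
                   what, which(rows)[1L]), call. = FALSE)
  }
  if (nrow(tr) == 0L) stop("invalid session: empty trial table", call. = FALSE)
  fail(c(FALSE, diff(tr$trial) <= 0), "trial indices not strictly increasing")
  fail(!tr$red_side %in% c("L", "R"), "red_side outside {L, R}")
  fail(!(tr$red_pos %in% 1:6), "red_pos outside 1..6")
  fail((tr$red_pos <= 3L) != (tr$red_side == "L"),
       "red_pos inconsistent with red_side")
  fail(!tr$side_A %in% c("L", "R") | !tr$side_B %in% c("L", "R"),
       "side outside {L, R}")
  eval <- evaluate_trial(tr$red_side, tr$side_A, tr$side_B)
  fail(eval$choice_A != tr$choice_A | eval$choice_B != tr$choice_B,
       "choice label inconsistent with layout and side")
  fail(eval$reward_A != tr$reward_A | eval$reward_B != tr$reward_B,
       "rewards inconsistent with choices")
  fail(!tr$visible %in% c(0L, 1L), "visible flag outside {0, 1}")
  for (ag in c("A", "B")) {
    rel <- tr[[paste0("t_rel_", ag, "_ms")]]
    acq <- tr[[paste0("t_acq_", ag, "_ms")]]
    both <- !is.na(rel) & !is.na(acq)
    fail(both & rel >= acq, paste0("t_release not before t_acquisition (", ag, ")"))
    fail(both & rel <= 0, paste0("non-positive timestamps (", ag, ")"))
  }
  invisible(session)
}

#' @export
print.bos_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<bos_session> %d trials, pair %s/%s (%s, %s)\n",
              nrow(tr), x$agents[1], x$agents[2], x$species, x$condition))
  cat(sprintf("  coordination: %.1f%%, mean joint reward: %.3f\n",
              100 * mean(tr$reward_A + tr$reward_B >= 7),
              mean((tr$reward_A + tr$reward_B) / 2)))
  invisible(x)
}

# Run expr-free seeding without clobbering the caller's RNG state: the
# previous .Random.seed is restored when the calling function exits.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    do.call(on.exit, list(quote(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    ), add = TRUE), envir = env)
    assign("old", old, envir = env)
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  invisible(NULL)
}
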