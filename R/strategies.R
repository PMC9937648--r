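# Parametrised agent policies for the session simulator.
#
# A strategy is a small S3 object (class "bos_strategy") describing how an
# agent picks a colour category ("own"/"other") on each trial before any
# within-trial information about the partner is available. The
# leader-follower strategy wraps a baseline policy and adds the
# action-visibility gate applied by simulate_session().

new_strategy <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "bos_strategy")
}

#' Agent strategies for the session simulator
#'
#' Constructors for the policy repertoire observed in transparent BoS
#' sessions:
#' \describe{
#'   \item{`strategy_fixed_color(which)`}{always select the own (`"own"`) or
#'     the partner's (`"other"`) preferred colour.}
#'   \item{`strategy_fixed_side(side)`}{always select one objective side,
#'     regardless of where the colours land.}
#'   \item{`strategy_trial_turn_taking(first)`}{strict trial-by-trial
#'     alternation of the jointly targeted colour; `first` names the agent
#'     (`"A"` or `"B"`) whose preferred colour is taken on trial 1. Both
#'     agents constructed with the same `first` are phase-aligned and
#'     coordinate on every trial.}
#'   \item{`strategy_block_turn_taking(block_len, first)`}{as above but the
#'     jointly targeted colour alternates in blocks of `block_len` trials.}
#'   \item{`strategy_confederate(block_len, jitter, first_color)`}{scripted
#'     block alternation between the two physical colours in blocks of
#'     approximately `block_len` (default 20) trials, the policy used by a
#'     human confederate during training; `jitter` adds a uniform
#'     +/- jitter to each block length, and `first_color` (`"red"`,
#'     `"blue"` or `NULL` for a random draw) sets the starting colour.}
#'   \item{`strategy_leader_follower(baseline, follow_fidelity)`}{play
#'     `baseline` (another strategy), but when the partner moves first and
#'     the trial is transparent, copy the partner's physical target with
#'     probability `psee(dt) * follow_fidelity`, where `dt` is the
#'     action-time difference (see [psee()]).}
#'   \item{`strategy_random(p_own)`}{select the own colour independently
#'     with probability `p_own` on each trial.}
#' }
#'
#' @param which `"own"` or `"other"`.
#' @param side `"left"` or `"right"` (objective frame).
#' @param first `"A"` or `"B"`: whose preferred colour is targeted first.
#' @param block_len block length in trials (>= 1).
#' @param jitter non-negative integer, maximal uniform jitter of the
#'   confederate block length.
#' @param first_color `"red"`, `"blue"`, or `NULL` to draw at random.
#' @param baseline a `bos_strategy` providing the leader-follower agent's
#'   default choice when it does not follow.
#' @param follow_fidelity probability in \[0, 1\] of following given that
#'   the partner's action was seen.
#' @param p_own probability in \[0, 1\] of choosing the own colour.
#' @return A `bos_strategy` object.
#' @name strategies
NULL

#' @rdname strategies
#' @export
strategy_fixed_color <- function(which = c("own", "other")) {
  new_strategy("fixed_color", which = match.arg(which))
}

#' @rdname strategies
#' @export
strategy_fixed_side <- function(side = c("left", "right")) {
  new_strategy("fixed_side", side = c(left = "L", right = "R")[match.arg(side)])
}

#' @rdname strategies
#' @export
strategy_trial_turn_taking <- function(first = c("A", "B")) {
  new_strategy("trial_turn_taking", first = match.arg(first))
}

#' @rdname strategies
#' @export
strategy_block_turn_taking <- function(block_len, first = c("A", "B")) {
  if (block_len < 1) stop("'block_len' must be >= 1")
  new_strategy("block_turn_taking", block_len = as.integer(block_len),
               first = match.arg(first))
}

#' @rdname strategies
#' @export
strategy_confederate <- function(block_len = 20L, jitter = 0L,
                                 first_color = NULL) {
  if (block_len < 1) stop("'block_len' must be >= 1")
  stopifnot(jitter >= 0, jitter < block_len)
  if (!is.null(first_color)) stopifnot(first_color %in% c("red", "blue"))
  new_strategy("confederate", block_len = as.integer(block_len),
               jitter = as.integer(jitter), first_color = first_color)
}

#' @rdname strategies
#' @export
strategy_leader_follower <- function(baseline = strategy_fixed_color("own"),
                                     follow_fidelity = 1) {
  stopifnot(inherits(baseline, "bos_strategy"),
            follow_fidelity >= 0, follow_fidelity <= 1)
  new_strategy("leader_follower", baseline = baseline,
               follow_fidelity = follow_fidelity)
}

#' @rdname strategies
#' @export
strategy_random <- function(p_own = 0.5) {
  stopifnot(p_own >= 0, p_own <= 1)
  new_strategy("random", p_own = p_own)
}

#' @export
print.bos_strategy <- function(x, ...) {
  extra <- x[setdiff(names(x), "kind")]
  extra <- vapply(extra, function(v)
    if (inherits(v, "bos_strategy")) paste0("<", v$kind, ">")
    else paste(format(v), collapse = ","), character(1))
  cat(sprintf("<bos_strategy> %s(%s)\n", x$kind,
              paste(names(extra), extra, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Scripted confederate colour plan
#'
#' Builds the per-trial colour plan of a scripted confederate who
#' alternates between the two physical colours in blocks of approximately
#' `block_len` trials.
#'
#' @param n_trials number of trials.
#' @param block_len nominal block length (default 20 trials).
#' @param jitter maximal uniform jitter (in trials) applied independently
#'   to every block length; 0 gives exact blocks.
#' @param seed integer seed (used for the starting colour when
#'   `first_color` is `NULL` and for the jitter draws).
#' @param first_color `"red"`, `"blue"` or `NULL` (random).
#' @return Character vector of length `n_trials` over `{"red", "blue"}`.
#' @export
confederate_schedule <- function(n_trials, block_len = 20L, jitter = 0L,
                                 seed = 1L, first_color = NULL) {
  if (block_len < 1) stop("'block_len' must be >= 1")
  stopifnot(n_trials >= 1, jitter >= 0, jitter < block_len)
  local_seed(seed)
  confederate_plan(n_trials, block_len, jitter, first_color)
}

# Internal: draws from the current RNG stream (no seeding).
confederate_plan <- function(n_trials, block_len, jitter, first_color) {
  if (is.null(first_color)) first_color <- sample(c("red", "blue"), 1L)
  colors <- c(first_color, setdiff(c("red", "blue"), first_color))
  plan <- character(0)
  b <- 0L
  while (length(plan) < n_trials) {
    len <- block_len
    if (jitter > 0) len <- block_len + sample(seq(-jitter, jitter), 1L)
    plan <- c(plan, rep(colors[(b %% 2L) + 1L], max(1L, len)))
    b <- b + 1L
  }
  plan[seq_len(n_trials)]
}

# Baseline colour-category choice of a strategy on one trial.
# role: "A" or "B"; plan: precomputed confederate plan or NULL.
# Consumes the RNG stream only for the "random" kind.
baseline_choice <- function(strategy, role, t, red_side, plan = NULL) {
  pref_color <- if (role == "A") "red" else "blue"
  switch(strategy$kind,
    fixed_color = strategy$which,
    fixed_side = {
      own_side <- if (role == "A") red_side else setdiff(c("L", "R"), red_side)
      if (strategy$side == own_side) "own" else "other"
    },
    trial_turn_taking = {
      turn <- if (t %% 2L == 1L) strategy$first
              else setdiff(c("A", "B"), strategy$first)
      if (turn == role) "own" else "other"
    },
    block_turn_taking = {
      b <- ((t - 1L) %/% strategy$block_len) %% 2L
      turn <- if (b == 0L) strategy$first else setdiff(c("A", "B"), strategy$first)
      if (turn == role) "own" else "other"
    },
    confederate = if (plan[t] == pref_color) "own" else "other",
    leader_follower = baseline_choice(strategy$baseline, role, t, red_side, plan),
    random = if (stats::runif(1) < strategy$p_own) "own" else "other",
    stop("unknown strategy kind: ", strategy$kind)
  )
}

# Objective side on which `choice` lands for `role` under the layout.
choice_to_side <- function(choice, role, red_side) {
  pref_side <- if (role == "A") red_side else setdiff(c("L", "R"), red_side)
  if (choice == "own") pref_side else setdiff(c("L", "R"), pref_side)
}
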