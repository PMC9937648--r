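# Session-level choice metrics: fractions of choosing own / left, average
# and joint reward, coordination fraction, analysis windows.

trailing_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
}

metric_series <- function(measure, agent, scalar, series, w) {
  structure(list(measure = measure, agent = agent, scalar = scalar,
                 series = series, w = w), class = "bos_metric_series")
}

#' @export
print.bos_metric_series <- function(x, ...) {
  cat(sprintf("<bos_metric_series> %s(%s): %.4f over %d trials (w = %d)\n",
              x$measure, x$agent, x$scalar, length(x$series), x$w))
  invisible(x)
}

fraction_metric <- function(session, agent, indicator, measure, w) {
  stopifnot(inherits(session, "bos_session"))
  if (!agent %in% c("A", "B"))
    stop("unknown agent label: ", agent, " (use \"A\" or \"B\")")
  stopifnot(w >= 1)
  x <- as.numeric(indicator)
  metric_series(measure, agent, scalar = mean(x),
                series = trailing_mean(x, w), w = as.integer(w))
}

#' Fraction of choosing own (FCO)
#'
#' Fraction of trials in which an agent selected its individually preferred
#' colour. The scalar value is computed over the whole supplied session
#' (use [last_n()] first for the steady-state convention); the series is a
#' trailing running average over `w` trials, so it can only take the values
#' 0, 1/w, 2/w, ..., 1 and is undefined (`NA`) for the first `w - 1`
#' trials.
#'
#' @param session a `bos_session`.
#' @param agent `"A"` or `"B"`.
#' @param w running-window width in trials (default 8).
#' @return A `bos_metric_series` with elements `scalar` and `series`.
#' @export
fco <- function(session, agent, w = 8L) {
  ch <- session$trials[[paste0("choice_", agent)]]
  fraction_metric(session, agent, ch == "own", "FCO", w)
}

#' Fraction of choosing the objective left side (FCL)
#'
#' Fraction of trials in which an agent selected the target on the
#' objective left side (sides are expressed in agent A's frame for both
#' agents). Same contract as [fco()].
#'
#' @inheritParams fco
#' @export
fcl <- function(session, agent, w = 8L) {
  sd <- session$trials[[paste0("side_", agent)]]
  fraction_metric(session, agent, sd == "L", "FCL", w)
}

#' Average reward of an agent or of the pair
#'
#' Per-agent mean payoff (range 1 to 4 reward units) or the mean joint
#' reward of the pair, `(reward_A + reward_B) / 2`, which cannot exceed 3.5
#' because on a coordinated trial one agent earns 4 and the other 3.
#'
#' @param session a `bos_session`.
#' @param who `"pair"` (default), `"A"` or `"B"`.
#' @return Mean reward in units of the payoff matrix.
#' @export
average_reward <- function(session, who = c("pair", "A", "B")) {
  who <- match.arg(who)
  tr <- session$trials
  if (nrow(tr) == 0L) stop("empty session")
  switch(who,
         pair = mean((tr$reward_A + tr$reward_B) / 2),
         A = mean(tr$reward_A),
         B = mean(tr$reward_B))
}

#' Fraction of coordinated trials
#' @param session a `bos_session`.
#' @export
coordination_fraction <- function(session) {
  tr <- session$trials
  mean(tr$choice_A != tr$choice_B)
}

#' Final analysis window of a session
#'
#' Returns the last `n` trials of a session, the convention used to assess
#' steady-state behaviour after an initial exploration period. Sessions
#' shorter than `n` are returned whole and flagged
#' (`meta$short_session = TRUE`) rather than rejected, since some recorded
#' sessions or segments are short.
#'
#' @param session a `bos_session`.
#' @param n window length in trials (default 200).
#' @return A `bos_session` containing the final `min(n, n_trials)` trials.
#' @export
last_n <- function(session, n = 200L) {
  ntr <- n_trials(session)
  keep <- seq.int(max(1L, ntr - n + 1L), ntr)
  out <- session
  out$trials <- session$trials[keep, , drop = FALSE]
  rownames(out$trials) <- NULL
  out$meta$short_session <- ntr < n
  out
}

#' Change in coordination between two session windows
#'
#' Fisher's exact test on the 2x2 table of coordinated/uncoordinated trial
#' counts in an early versus a late window, as used to assess whether the
#' proportion of coordinated trials increased within a session. The
#' reported odds ratio is the sample odds ratio
#' `odds(late) / odds(early)`; the p-value is the two-sided exact
#' probability (a Bonferroni factor, when several sessions are tested, is
#' applied by the caller). A degenerate table in which all trials fall in
#' one category is flagged and assigned p = 1 by convention.
#'
#' @param early_session,late_session `bos_session` objects.
#' @return List with `odds_ratio`, `p_value`, `table`, `degenerate`.
#' @export
coordination_change_test <- function(early_session, late_session) {
  counts <- vapply(list(early = early_session, late = late_session),
                   function(s) {
                     co <- s$trials$choice_A != s$trials$choice_B
                     c(coord = sum(co), uncoord = sum(!co))
                   }, numeric(2))
  tab <- t(counts)  # rows early/late, cols coord/uncoord
  degenerate <- any(colSums(tab) == 0)
  if (degenerate) {
    or <- NA_real_
    p <- 1
  } else {
    or <- (tab["late", "coord"] / tab["late", "uncoord"]) /
      (tab["early", "coord"] / tab["early", "uncoord"])
    p <- stats::fisher.test(tab)$p.value
  }
  list(odds_ratio = unname(or), p_value = p, table = tab,
       degenerate = degenerate)
}
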