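# Action times, Welch action-time difference tests, the logistic action
# visibility model (psee), and the visibility-following correlation.

#' Movement and action time from release/acquisition timestamps
#'
#' The movement time is `t_acquisition - t_release`; the action time is
#' the halfway point of the reach, `t_release + t_movement / 2`, used as a
#' proxy for the moment at which the movement becomes readable by the
#' partner.
#'
#' @param t_release,t_acquisition timestamps in ms from the go signal
#'   (vectors of equal length; `NA` allowed and propagated).
#' @return data.frame with columns `t_release`, `t_acquisition`,
#'   `t_movement`, `t_action`.
#' @examples
#' action_time(200, 400)  # movement 200 ms, action time 300 ms
#' @export
action_time <- function(t_release, t_acquisition) {
  stopifnot(length(t_release) == length(t_acquisition))
  bad <- !is.na(t_release) & !is.na(t_acquisition) & t_release > t_acquisition
  if (any(bad))
    stop(sprintf("t_release after t_acquisition (first offending element %d)",
                 which(bad)[1L]))
  mv <- t_acquisition - t_release
  data.frame(t_release = t_release, t_acquisition = t_acquisition,
             t_movement = mv, t_action = t_release + mv / 2)
}

#' Per-trial action times of both agents in a session
#'
#' @param session a `bos_session`.
#' @return data.frame with `trial`, `at_A`, `at_B` (ms; `NA` where
#'   timestamps are missing).
#' @export
session_action_times <- function(session) {
  tr <- session$trials
  data.frame(trial = tr$trial,
             at_A = action_time(tr$t_rel_A_ms, tr$t_acq_A_ms)$t_action,
             at_B = action_time(tr$t_rel_B_ms, tr$t_acq_B_ms)$t_action)
}

welch_result <- function(test, g1, g2) {
  ok <- length(g1) >= 2L && length(g2) >= 2L &&
    (stats::sd(g1) > 0 || stats::sd(g2) > 0)
  if (!ok)
    return(list(test = test, computable = FALSE, t = NA_real_, df = NA_real_,
                p = NA_real_, mean1 = mean(g1), sd1 = stats::sd(g1),
                n1 = length(g1), mean2 = mean(g2), sd2 = stats::sd(g2),
                n2 = length(g2)))
  ht <- stats::t.test(g1, g2, var.equal = FALSE)
  list(test = test, computable = TRUE,
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean1 = mean(g1), sd1 = stats::sd(g1), n1 = length(g1),
       mean2 = mean(g2), sd2 = stats::sd(g2), n2 = length(g2))
}

#' Action-time difference tests
#'
#' The three Welch (Satterthwaite-approximated) two-sample t-tests used to
#' characterise temporal leader-follower structure in a dyad:
#' \enumerate{
#'   \item all-trial action times of agent A versus agent B (stable
#'     temporal leadership);
#'   \item the per-trial action-time difference `AT_A - AT_B` in
#'     coordinated trials on A's preferred colour versus coordinated
#'     trials on B's preferred colour (who waits for whom during each
#'     coordination mode);
#'   \item the absolute per-trial difference `|AT_A - AT_B|` in
#'     coordinated versus uncoordinated trials (whether agents wait for
#'     each other more when coordinating).
#' }
#' Trials with a missing action time for either agent are dropped
#' pairwise. A comparison whose groups have fewer than two usable trials
#' is flagged `computable = FALSE`.
#'
#' @param session a `bos_session` with timestamps.
#' @return List of three result records (`at_A_vs_B`,
#'   `atdiff_coordA_vs_coordB`, `absdiff_coord_vs_uncoord`), each with
#'   `t`, `df` (Satterthwaite), two-sided `p`, group means/SDs/Ns and a
#'   `computable` flag. Differences follow the `AT_A - AT_B` convention.
#' @export
at_tests <- function(session) {
  at <- session_action_times(session)
  tr <- session$trials
  ok <- !is.na(at$at_A) & !is.na(at$at_B)
  dt <- at$at_A[ok] - at$at_B[ok]
  coord <- (tr$choice_A != tr$choice_B)[ok]
  on_a <- coord & tr$choice_A[ok] == "own"
  on_b <- coord & tr$choice_A[ok] == "other"
  list(
    at_A_vs_B = welch_result("AT A vs AT B (all trials)",
                             at$at_A[ok], at$at_B[ok]),
    atdiff_coordA_vs_coordB =
      welch_result("AT difference: coordination on A's vs B's color",
                   dt[on_a], dt[on_b]),
    absdiff_coord_vs_uncoord =
      welch_result("|AT difference|: coordinated vs uncoordinated",
                   abs(dt[coord]), abs(dt[!coord]))
  )
}

#' Logistic probability of seeing the partner's choice
#'
#' Models the probability that an agent sees the partner's choice before
#' committing to its own as a logistic function of the action-time
#' difference `dt` (positive when the agent is slower than the partner):
#' `psee(dt) = 1 / (1 + exp(-k (dt - dt0)))`. With the default steepness
#' `k = 0.04` per ms and inflection point `dt0 = 50` ms, `psee(50) = 0.5`
#' and `psee(150) = 0.98` (the plateau).
#'
#' @param dt action-time difference in ms (vectorised).
#' @param k slope, 1/ms (> 0).
#' @param dt0 inflection point, ms.
#' @return Probabilities in (0, 1), strictly increasing in `dt`.
#' @export
psee <- function(dt, k = 0.04, dt0 = 50) {
  stopifnot(k > 0)
  1 / (1 + exp(-k * (dt - dt0)))
}

smooth_or_na <- function(x, w) trailing_mean(x, w)

cor_record <- function(ps, foll, w, n_perm, use_perm_seed) {
  valid <- !is.na(ps) & !is.na(foll)
  ps <- ps[valid]; foll <- foll[valid]
  res <- list(n = length(ps), r_raw = NA_real_, p_raw = NA_real_,
              r_smoothed = NA_real_, p_smoothed = NA_real_,
              p_raw_shuffle = NA_real_, undefined = FALSE)
  if (length(ps) < 3L || stats::sd(ps) == 0 || stats::sd(foll) == 0) {
    res$undefined <- TRUE
    return(res)
  }
  ct <- stats::cor.test(ps, foll)
  res$r_raw <- unname(ct$estimate); res$p_raw <- ct$p.value
  ps_s <- smooth_or_na(ps, w); foll_s <- smooth_or_na(foll, w)
  keep <- !is.na(ps_s) & !is.na(foll_s)
  if (sum(keep) >= 3L && stats::sd(ps_s[keep]) > 0 &&
      stats::sd(foll_s[keep]) > 0) {
    cs <- stats::cor.test(ps_s[keep], foll_s[keep])
    res$r_smoothed <- unname(cs$estimate); res$p_smoothed <- cs$p.value
  }
  if (n_perm > 0) {
    r_null <- vapply(seq_len(n_perm), function(j)
      stats::cor(ps, sample(foll)), numeric(1))
    res$p_raw_shuffle <- mean(abs(r_null) >= abs(res$r_raw))
  }
  res
}

#' Correlation between action visibility and following
#'
#' For each agent i, relates the modelled probability of seeing the
#' partner move first, `psee(AT_i - AT_partner)` (positive differences
#' mean agent i is slower and can watch the partner), to the agent's
#' probability of following to the partner's preferred colour, i.e. the
#' per-trial indicator of choosing other's (`1 - FCO` at the trial level).
#' Pearson correlations are reported both for the raw trial-by-trial
#' series and after trailing `w`-trial running averages of both series;
#' p-values come from the standard t transform, and an optional
#' permutation null (shuffling the following indicator) is available
#' because smoothing inflates autocorrelation.
#'
#' Trials with a missing action time for either agent are dropped
#' pairwise. If either series is constant the correlation is undefined
#' and flagged.
#'
#' @param session a `bos_session` with timestamps.
#' @param w running-window width (default 8 trials).
#' @param k,dt0 parameters of [psee()].
#' @param n_perm number of shuffles for the permutation p-value
#'   (0 = skip).
#' @param seed seed for the permutation null.
#' @return List with one record per agent (`A`, `B`): `r_raw`, `p_raw`,
#'   `r_smoothed`, `p_smoothed`, `p_raw_shuffle`, `n`, `undefined`.
#' @export
visibility_correlation <- function(session, w = 8L, k = 0.04, dt0 = 50,
                                   n_perm = 0L, seed = 1L) {
  at <- session_action_times(session)
  tr <- session$trials
  local_seed(seed)
  out <- list()
  for (ag in c("A", "B")) {
    other <- setdiff(c("A", "B"), ag)
    dt <- at[[paste0("at_", ag)]] - at[[paste0("at_", other)]]
    ps <- psee(dt, k, dt0)
    foll <- as.numeric(tr[[paste0("choice_", ag)]] == "other")
    out[[ag]] <- cor_record(ps, foll, w, n_perm, seed)
  }
  out
}

#' Robustness of the visibility correlation over psee parameters
#'
#' Re-evaluates [visibility_correlation()] over a grid of logistic
#' parameters: each `dt0` in `dt0_grid` with `k` fixed at `k_fixed`, then
#' each `k` in `k_grid` with `dt0` fixed at `dt0_fixed` (defaults give the
#' standard 6 + 5 = 11 settings).
#'
#' @param session a `bos_session` with timestamps.
#' @param dt0_grid inflection points (ms) evaluated at fixed slope.
#' @param k_grid slopes (1/ms) evaluated at fixed inflection point.
#' @param k_fixed,dt0_fixed the fixed counterparts of the two sweeps.
#' @param w running-window width.
#' @return data.frame with one row per setting: `k`, `dt0`, and per-agent
#'   raw and smoothed correlations (`NA` where undefined).
#' @export
psee_robustness <- function(session,
                            dt0_grid = c(12.5, 25, 50, 75, 100, 200),
                            k_grid = c(0.01, 0.02, 0.04, 0.08, 0.16),
                            k_fixed = 0.04, dt0_fixed = 50, w = 8L) {
  settings <- rbind(data.frame(k = k_fixed, dt0 = dt0_grid),
                    data.frame(k = k_grid, dt0 = dt0_fixed))
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    vc <- visibility_correlation(session, w = w, k = settings$k[i],
                                 dt0 = settings$dt0[i])
    data.frame(k = settings$k[i], dt0 = settings$dt0[i],
               r_raw_A = vc$A$r_raw, r_smoothed_A = vc$A$r_smoothed,
               r_raw_B = vc$B$r_raw, r_smoothed_B = vc$B$r_smoothed,
               undefined = vc$A$undefined && vc$B$undefined)
  })
  do.call(rbind, rows)
}
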