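# Coordination-block segmentation and switching behaviour: seamless
# switches, selfish vs benevolent choices of the faster agent, and
# uncoordinated-trial classes.

# Per-trial coordination mode.
trial_modes <- function(session) {
  tr <- session$trials
  ifelse(tr$choice_A != tr$choice_B,
         ifelse(tr$choice_A == "own", "coord_on_A_color", "coord_on_B_color"),
         ifelse(tr$choice_A == "own", "own_own", "other_other"))
}

#' Segment a session into coordination blocks
#'
#' Partitions the trials into maximal segments of constant coordination
#' mode. Coordinated trials are keyed by which agent's preferred colour
#' was jointly chosen (`coord_on_A_color` / `coord_on_B_color`);
#' consecutive uncoordinated trials are merged into one segment labelled
#' `own_own` or `other_other` when pure and `mixed_uncoordinated` when
#' both uncoordinated outcomes occur inside it.
#'
#' @param session a `bos_session`.
#' @return data.frame with columns `start`, `end` (trial positions,
#'   1-based), `mode`, `length`; the segments partition the session and
#'   consecutive segments differ in mode.
#' @export
segment_coordination <- function(session) {
  modes <- trial_modes(session)
  key <- ifelse(modes %in% c("coord_on_A_color", "coord_on_B_color"),
                modes, "uncoord")
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  mode <- r$values
  for (i in which(mode == "uncoord")) {
    inside <- unique(modes[start[i]:end[i]])
    mode[i] <- if (length(inside) == 1L) inside else "mixed_uncoordinated"
  }
  data.frame(start = start, end = end, mode = mode, length = r$lengths,
             stringsAsFactors = FALSE)
}

binom_verdict <- function(n_high, n_total) {
  # two-sided exact binomial CI on the proportion n_high / n_total vs 0.5
  if (n_total == 0L)
    return(list(ci_low = NA_real_, ci_high = NA_real_,
                verdict = "not_applicable"))
  ci <- stats::binom.test(n_high, n_total)$conf.int
  verdict <- if (ci[1] > 0.5) "benevolent"
             else if (ci[2] < 0.5) "selfish"
             else "balanced"
  list(ci_low = ci[1], ci_high = ci[2], verdict = verdict)
}

#' Seamless switches between coordination modes
#'
#' A seamless switch is a pair of consecutive coordinated trials whose
#' coordination colour differs (the pair changes from jointly selecting
#' one agent's preferred colour to the other's with no intervening
#' uncoordinated trial). For each switch the agent with the smaller
#' action time on the second (switch) trial is the faster agent; its
#' choice on that trial is classified as selfish (`"own"`) or benevolent
#' (`"other"`). Switches with missing action times or exact ties are
#' counted but left unattributed.
#'
#' The balance verdict compares the benevolent proportion among
#' attributed switches to 0.5 with an exact binomial 95% confidence
#' interval: `"balanced"` when 0.5 lies inside, `"selfish"`/`"benevolent"`
#' when the interval falls below/above 0.5, `"not_applicable"` with no
#' attributed switches.
#'
#' @param session a `bos_session`.
#' @return List of class `bos_switch_tally`: `n_switches`, `n_selfish`,
#'   `n_benevolent`, `n_unattributed`, `ci_low`, `ci_high`, `verdict`,
#'   and `switches`, a per-switch data.frame (`trial`, `from`, `to`,
#'   `faster`, `choice`, `class`).
#' @export
seamless_switches <- function(session) {
  modes <- trial_modes(session)
  at <- session_action_times(session)
  n <- length(modes)
  coord <- modes %in% c("coord_on_A_color", "coord_on_B_color")
  idx <- which(coord[-1L] & coord[-n] & modes[-1L] != modes[-n]) + 1L
  recs <- lapply(idx, function(t) {
    a <- at$at_A[t]; b <- at$at_B[t]
    if (is.na(a) || is.na(b) || a == b)
      return(data.frame(trial = session$trials$trial[t],
                        from = modes[t - 1L], to = modes[t],
                        faster = NA_character_, choice = NA_character_,
                        class = "unattributed", stringsAsFactors = FALSE))
    faster <- if (a < b) "A" else "B"
    choice <- session$trials[[paste0("choice_", faster)]][t]
    data.frame(trial = session$trials$trial[t],
               from = modes[t - 1L], to = modes[t], faster = faster,
               choice = choice,
               class = if (choice == "own") "selfish" else "benevolent",
               stringsAsFactors = FALSE)
  })
  switches <- if (length(recs)) do.call(rbind, recs)
    else data.frame(trial = integer(0), from = character(0),
                    to = character(0), faster = character(0),
                    choice = character(0), class = character(0))
  n_self <- sum(switches$class == "selfish")
  n_ben <- sum(switches$class == "benevolent")
  bv <- binom_verdict(n_ben, n_self + n_ben)
  structure(list(n_switches = nrow(switches), n_selfish = n_self,
                 n_benevolent = n_ben,
                 n_unattributed = sum(switches$class == "unattributed"),
                 ci_low = bv$ci_low, ci_high = bv$ci_high,
                 verdict = bv$verdict, switches = switches),
            class = "bos_switch_tally")
}

#' @export
print.bos_switch_tally <- function(x, ...) {
  cat(sprintf("<bos_switch_tally> %d seamless switches: %d selfish, %d benevolent, %d unattributed -> %s\n",
              x$n_switches, x$n_selfish, x$n_benevolent, x$n_unattributed,
              x$verdict))
  invisible(x)
}

#' Classes of uncoordinated trials
#'
#' Counts uncoordinated trials in which both agents selected their own
#' preferred colour (`own_own`) versus both selecting the non-preferred
#' colour (`other_other`), with an exact binomial 95% confidence interval
#' on the `other_other` proportion against the diagonal (0.5). Pairs
#' below the diagonal band (`ci_high < 0.5`) are verdicted `"selfish"`,
#' above it `"benevolent"`, otherwise `"balanced"`;
#' `"not_applicable"` when the session has no uncoordinated trials.
#'
#' @param session a `bos_session`.
#' @return List with `n_own_own`, `n_other_other`, `ci_low`, `ci_high`,
#'   `verdict`.
#' @export
uncoordinated_classes <- function(session) {
  modes <- trial_modes(session)
  n_oo <- sum(modes == "own_own")
  n_tt <- sum(modes == "other_other")
  bv <- binom_verdict(n_tt, n_oo + n_tt)
  list(n_own_own = n_oo, n_other_other = n_tt,
       ci_low = bv$ci_low, ci_high = bv$ci_high, verdict = bv$verdict)
}

#' Action-time profile around coordination transitions
#'
#' Aligns per-agent action times on the transitions between coordination
#' and non-coordination and averages them by trial offset. Transition
#' trials are the first trial of each segment that changes the
#' coordination status (types `to_coordination` and `from_coordination`);
#' transitions closer than `halfwidth` trials to the session edges are
#' excluded.
#'
#' @param session a `bos_session` with timestamps.
#' @param halfwidth number of trials on each side of the transition
#'   (default 3).
#' @return data.frame with columns `type`, `offset`
#'   (-halfwidth..halfwidth), `at_A`, `at_B` (mean action times, ms) and
#'   `n` (transitions contributing); zero rows when the session has no
#'   usable transitions.
#' @export
transition_at_profile <- function(session, halfwidth = 3L) {
  seg <- segment_coordination(session)
  at <- session_action_times(session)
  n <- n_trials(session)
  is_coord <- seg$mode %in% c("coord_on_A_color", "coord_on_B_color")
  trans <- data.frame(t = integer(0), type = character(0))
  if (nrow(seg) > 1L) {
    starts <- seg$start[-1L]
    types <- ifelse(is_coord[-1L] & !is_coord[-nrow(seg)],
                    "to_coordination",
                    ifelse(!is_coord[-1L] & is_coord[-nrow(seg)],
                           "from_coordination", NA))
    keep <- !is.na(types)
    trans <- data.frame(t = starts[keep], type = types[keep],
                        stringsAsFactors = FALSE)
  }
  trans <- trans[trans$t - halfwidth >= 1L & trans$t + halfwidth <= n, ,
                 drop = FALSE]
  if (nrow(trans) == 0L)
    return(data.frame(type = character(0), offset = integer(0),
                      at_A = numeric(0), at_B = numeric(0), n = integer(0)))
  offsets <- seq.int(-halfwidth, halfwidth)
  rows <- lapply(unique(trans$type), function(tp) {
    tt <- trans$t[trans$type == tp]
    do.call(rbind, lapply(offsets, function(o) {
      data.frame(type = tp, offset = o,
                 at_A = mean(at$at_A[tt + o], na.rm = TRUE),
                 at_B = mean(at$at_B[tt + o], na.rm = TRUE),
                 n = length(tt), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
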