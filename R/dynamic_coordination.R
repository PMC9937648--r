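# Random-play reward baseline (RPR), dynamic coordination reward (DCR),
# its confidence interval, and MI-plane strategy classification.

#' Empirical choice probabilities of a session
#'
#' Estimates, for each agent i, the four joint probabilities
#' `P(i, c, side)` of selecting the non-preferred (`c = 1`) or preferred
#' (`c = 2`) colour when it sits on the objective left or right side,
#' together with the layout frequencies `Q_left`/`Q_right` (probability of
#' agent A's preferred colour appearing on the left/right). The four P
#' values of an agent sum to 1, and the cross constraints
#' `P[i,2,left] + P[i,1,right] = Q_left` (for A; the mirrored identity for
#' B) hold exactly for empirical frequencies.
#'
#' @param session a `bos_session`.
#' @return An object of class `bos_choice_probs`: list with `P` (a
#'   `2 x 2 x 2` array indexed by agent, colour category, side), `q_left`,
#'   `q_right`, `n`.
#' @export
choice_probs <- function(session) {
  tr <- session$trials
  if (nrow(tr) == 0L) stop("empty session")
  P <- array(0, dim = c(2, 2, 2),
             dimnames = list(agent = c("A", "B"),
                             color = c("nonpref", "pref"),
                             side = c("left", "right")))
  n <- nrow(tr)
  for (ag in c("A", "B")) {
    ch <- tr[[paste0("choice_", ag)]]
    sd <- tr[[paste0("side_", ag)]]
    for (cc in c("own", "other")) for (ss in c("L", "R")) {
      P[ag, if (cc == "own") "pref" else "nonpref",
        if (ss == "L") "left" else "right"] <- sum(ch == cc & sd == ss) / n
    }
  }
  structure(list(P = P, q_left = mean(tr$red_side == "L"),
                 q_right = mean(tr$red_side == "R"), n = n),
            class = "bos_choice_probs")
}

#' Choice probabilities reconstructed from FCO and FCL
#'
#' Given each agent's fraction of choosing own (FCO) and fraction of
#' choosing the objective left side (FCL), and the layout probability
#' `q_left`, the four per-agent probabilities are fully determined:
#' `P[i,2,left] = (FCO_i + FCL_i - q_other_side) / 2` and the remaining
#' three follow from the marginal and layout constraints. This is the
#' parametrisation used for the DCR confidence interval, where the
#' layout probabilities are fixed at 0.5. Values pushed outside \[0, 1\]
#' by confidence-interval corners are clipped.
#'
#' @param fco_a,fcl_a,fco_b,fcl_b per-agent fractions in \[0, 1\].
#' @param q_left layout probability (default 0.5).
#' @return A `bos_choice_probs` object.
#' @export
probs_from_fractions <- function(fco_a, fcl_a, fco_b, fcl_b, q_left = 0.5) {
  q_right <- 1 - q_left
  # Constraints: for A, P[1,left] + P[2,right] = q_right; for B,
  # P[1,left] + P[2,right] = q_left. Together with the FCO/FCL marginals
  # these pin down all four probabilities of each agent.
  pa <- {
    p2l <- (fco_a + fcl_a - q_right) / 2
    c(fcl_a - p2l, q_left - p2l, p2l, fco_a - p2l)
  }
  pb <- {
    p2l <- (fco_b + fcl_b - q_left) / 2
    c(fcl_b - p2l, q_right - p2l, p2l, fco_b - p2l)
  }
  P <- array(0, dim = c(2, 2, 2),
             dimnames = list(agent = c("A", "B"),
                             color = c("nonpref", "pref"),
                             side = c("left", "right")))
  P["A", "nonpref", "left"] <- pa[1]; P["A", "nonpref", "right"] <- pa[2]
  P["A", "pref", "left"] <- pa[3]; P["A", "pref", "right"] <- pa[4]
  P["B", "nonpref", "left"] <- pb[1]; P["B", "nonpref", "right"] <- pb[2]
  P["B", "pref", "left"] <- pb[3]; P["B", "pref", "right"] <- pb[4]
  P <- pmin(pmax(P, 0), 1)
  structure(list(P = P, q_left = q_left, q_right = q_right, n = NA_integer_),
            class = "bos_choice_probs")
}

#' Reward for playing randomly (RPR)
#'
#' Expected mean joint reward if the two agents' colour choices were
#' independent given the layout, keeping each agent's side-conditional
#' choice probabilities. With `p[a,b]` the probability that under such
#' random play agent A earns `a` and agent B earns `b`:
#' `RPR = 3.5 (p[4,3] + p[3,4]) + 2 p[2,2] + p[1,1]`, where each `p[a,b]`
#' sums, over the two layouts, the product of the agents' choice
#' probabilities conditional on that layout (hence the division by the
#' layout probabilities). RPR lies in \[1, 3.5\].
#'
#' @param probs a `bos_choice_probs` (from [choice_probs()] or
#'   [probs_from_fractions()]).
#' @return RPR in reward units.
#' @export
rpr <- function(probs) {
  stopifnot(inherits(probs, "bos_choice_probs"))
  if (probs$q_left <= 0 || probs$q_right <= 0)
    stop("RPR undefined: a layout probability (Q) is zero")
  P <- probs$P
  ql <- probs$q_left; qr <- probs$q_right
  p11 <- P["A", "nonpref", "right"] * P["B", "nonpref", "left"] / ql +
         P["A", "nonpref", "left"] * P["B", "nonpref", "right"] / qr
  p22 <- P["A", "pref", "left"] * P["B", "pref", "right"] / ql +
         P["A", "pref", "right"] * P["B", "pref", "left"] / qr
  p43 <- P["A", "pref", "left"] * P["B", "nonpref", "left"] / ql +
         P["A", "pref", "right"] * P["B", "nonpref", "right"] / qr
  p34 <- P["A", "nonpref", "right"] * P["B", "pref", "right"] / ql +
         P["A", "nonpref", "left"] * P["B", "pref", "left"] / qr
  unname(3.5 * (p43 + p34) + 2 * p22 + p11)
}

#' Dynamic coordination reward (DCR)
#'
#' DCR is the surplus mean joint reward of a pair over what the same
#' marginal choice behaviour would earn under random (history- and
#' partner-independent) play: `DCR = R_actual - RPR`, with range
#' \[-1, 1\]. +1 corresponds to maximally efficient dynamic coordination
#' (e.g. perfect turn-taking), -1 to alternating anti-coordination, and 0
#' to static play (e.g. both agents always selecting the same side, which
#' earns 3.5 but no more than its random-play baseline).
#'
#' The RPR inside DCR is computed from the agents' FCO/FCL via
#' [probs_from_fractions()] with the layout probabilities fixed at 0.5
#' (the design value of the balanced schedule); the empirical layout
#' frequencies are still reported in the diagnostics.
#'
#' The confidence interval combines the two estimated ingredients of DCR.
#' The baseline side treats each agent's FCO and FCL as binomial
#' proportions with normal-approximation radii `z * sqrt(p (1 - p) / n)`
#' and takes the minimum and maximum RPR over the 16 corners of the
#' 4-dimensional box (the RPR is multilinear in the four fractions, so
#' its extrema over the box are attained at corners; corner fractions are
#' clipped to \[0, 1\]). Because the observed mean joint reward is itself
#' a sample mean, the corner range is then widened on each side by
#' `z * sd(joint reward) / sqrt(n)`; without this term the interval
#' covers only the baseline uncertainty and rejects a true null far more
#' often than its nominal level (see the permutation-null property in the
#' package tests). The combination is conservative.
#'
#' @param session a `bos_session`.
#' @param ci_z normal quantile for the binomial confidence radii
#'   (default 1.96, a 95% interval).
#' @param q_left layout probability used inside the RPR (default 0.5).
#' @return An object of class `bos_dcr`: list with `r_actual`, `rpr`,
#'   `dcr`, `ci_low`, `ci_high`, `significant` (0 outside the interval),
#'   `n_trials`, `ci_z`, and the four `fractions`.
#' @export
dcr <- function(session, ci_z = 1.96, q_left = 0.5) {
  tr <- session$trials
  if (nrow(tr) == 0L) stop("empty session")
  n <- nrow(tr)
  r_actual <- mean((tr$reward_A + tr$reward_B) / 2)
  fr <- c(fco_a = mean(tr$choice_A == "own"),
          fcl_a = mean(tr$side_A == "L"),
          fco_b = mean(tr$choice_B == "own"),
          fcl_b = mean(tr$side_B == "L"))
  point_rpr <- rpr(probs_from_fractions(fr["fco_a"], fr["fcl_a"],
                                        fr["fco_b"], fr["fcl_b"], q_left))
  d <- r_actual - point_rpr
  delta <- ci_z * sqrt(fr * (1 - fr) / n)
  corners <- as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1),
                                   s3 = c(-1, 1), s4 = c(-1, 1)))
  corner_dcr <- apply(corners, 1L, function(s) {
    f <- pmin(pmax(fr + s * delta, 0), 1)
    r_actual - rpr(probs_from_fractions(f[1], f[2], f[3], f[4], q_left))
  })
  se_r <- ci_z * stats::sd((tr$reward_A + tr$reward_B) / 2) / sqrt(n)
  ci <- range(c(corner_dcr, d)) + c(-se_r, se_r)
  structure(list(r_actual = r_actual, rpr = point_rpr, dcr = d,
                 ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 n_trials = n, ci_z = ci_z, fractions = fr),
            class = "bos_dcr")
}

#' @export
print.bos_dcr <- function(x, ...) {
  cat(sprintf("<bos_dcr> DCR = %.4f [%.4f, %.4f]%s (R_actual = %.4f, RPR = %.4f, n = %d)\n",
              x$dcr, x$ci_low, x$ci_high,
              if (x$significant) " *" else "", x$r_actual, x$rpr, x$n_trials))
  invisible(x)
}

#' MI-plane strategy classification of a session
#'
#' Classifies the coordination pattern of a dyadic session from the
#' mutual-information plane (MI side vs MI colour) together with the DCR:
#' \describe{
#'   \item{`dynamic_turn_taking`}{significant DCR above `dcr_threshold`
#'     and significant MI for both colour and side choices.}
#'   \item{`static_color`}{significant MI side but not MI colour, with one
#'     fixed physical colour dominating the coordinated trials (both
#'     agents track one colour across sides).}
#'   \item{`static_side`}{significant MI colour but not MI side, with one
#'     objective side dominating the coordinated trials.}
#'   \item{`uncoordinated`}{coordination fraction not above the
#'     random-play expectation (one-sided binomial test).}
#'   \item{`unclassified`}{anything else.}
#' }
#'
#' @param session a `bos_session` (apply [last_n()] beforehand for the
#'   steady-state convention).
#' @param config an [analysis_config()]; supplies the MI significance
#'   level and surrogate count, the DCR threshold (default 0.2, strict
#'   inequality), the minimum session length, the dominance threshold for
#'   static patterns, and the seed.
#' @return List with `label` and a `diagnostics` list carrying the DCR
#'   and MI results, coordination fraction and dominance statistics.
#' @export
classify_strategy <- function(session, config = analysis_config()) {
  tr <- session$trials
  n <- nrow(tr)
  if (n < config$min_length)
    stop(sprintf("session too short to classify (%d < %d trials)",
                 n, config$min_length))
  d <- dcr(session, ci_z = config$dcr_z)
  mi_side <- mi_significance(side_series(session, "A"),
                             side_series(session, "B"),
                             alpha = config$mi_alpha,
                             n_surrogates = config$n_surrogates,
                             seed = config$seed)
  mi_color <- mi_significance(color_series(session, "A"),
                              color_series(session, "B"),
                              alpha = config$mi_alpha,
                              n_surrogates = config$n_surrogates,
                              seed = config$seed + 1L)
  coord <- tr$choice_A != tr$choice_B
  n_coord <- sum(coord)
  # dominance among coordinated trials
  dom_color <- dom_side <- NA_real_
  if (n_coord > 0) {
    joint_color <- ifelse(tr$choice_A[coord] == "own", "red", "blue")
    dom_color <- max(table(joint_color)) / n_coord
    dom_side <- max(table(tr$side_A[coord])) / n_coord
  }
  # expected coordination under random play with the same marginals
  pf <- probs_from_fractions(mean(tr$choice_A == "own"),
                             mean(tr$side_A == "L"),
                             mean(tr$choice_B == "own"),
                             mean(tr$side_B == "L"))
  P <- pf$P
  p_coord <- P["A", "pref", "left"] * P["B", "nonpref", "left"] / pf$q_left +
    P["A", "pref", "right"] * P["B", "nonpref", "right"] / pf$q_right +
    P["A", "nonpref", "right"] * P["B", "pref", "right"] / pf$q_left +
    P["A", "nonpref", "left"] * P["B", "pref", "left"] / pf$q_right
  p_coord <- min(max(p_coord, 0), 1)
  p_above <- if (p_coord >= 1) 1
             else stats::binom.test(n_coord, n, p_coord,
                                    alternative = "greater")$p.value
  label <-
    if (d$significant && d$dcr > config$dcr_threshold &&
        mi_side$significant && mi_color$significant) "dynamic_turn_taking"
    else if (mi_side$significant && !mi_color$significant &&
             !is.na(dom_color) && dom_color >= config$dominance) "static_color"
    else if (mi_color$significant && !mi_side$significant &&
             !is.na(dom_side) && dom_side >= config$dominance) "static_side"
    else if (p_above > 0.05) "uncoordinated"
    else "unclassified"
  list(label = label,
       diagnostics = list(dcr = d, mi_side = mi_side, mi_color = mi_color,
                          coordination_fraction = n_coord / n,
                          expected_coordination = unname(p_coord),
                          p_above_random = unname(p_above),
                          dominant_color_fraction = unname(dom_color),
                          dominant_side_fraction = unname(dom_side)))
}
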