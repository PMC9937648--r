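# Orchestration: analysis configuration, the full per-session metrics
# bundle, JSON serialisation, and tabular report helpers.

#' Analysis configuration
#'
#' Bundles the analysis constants with their standard defaults: the final
#' 200-trial steady-state window, 8-trial running windows, MI significance
#' level 0.01 with 1000 surrogate pairs, DCR confidence z of 1.96 and a
#' dynamic-coordination DCR threshold of 0.2, and the logistic visibility
#' parameters k = 0.04 per ms, dt0 = 50 ms.
#'
#' @param last_n steady-state window length (trials).
#' @param w running-window width (trials).
#' @param mi_alpha MI significance level.
#' @param n_surrogates surrogate pairs for MI significance.
#' @param dcr_z normal quantile for the DCR confidence interval.
#' @param dcr_threshold DCR amplitude (strict) required for dynamic
#'   coordination.
#' @param psee_k,psee_dt0 logistic visibility parameters.
#' @param min_length minimum session length for classification.
#' @param dominance fraction of coordinated trials one colour/side must
#'   reach to call a static pattern.
#' @param seed integer seed governing all stochastic analysis steps.
#' @return List of class `bos_config`.
#' @export
analysis_config <- function(last_n = 200L, w = 8L, mi_alpha = 0.01,
                            n_surrogates = 1000L, dcr_z = 1.96,
                            dcr_threshold = 0.2, psee_k = 0.04,
                            psee_dt0 = 50, min_length = 50L,
                            dominance = 0.75, seed = 1L) {
  structure(list(last_n = as.integer(last_n), w = as.integer(w),
                 mi_alpha = mi_alpha, n_surrogates = as.integer(n_surrogates),
                 dcr_z = dcr_z, dcr_threshold = dcr_threshold,
                 psee_k = psee_k, psee_dt0 = psee_dt0,
                 min_length = as.integer(min_length), dominance = dominance,
                 seed = as.integer(seed)),
            class = "bos_config")
}

strip_class <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_class) else x
}

#' Full metrics bundle for one session
#'
#' Runs the complete analysis battery on the steady-state window of a
#' session (the last `config$last_n` trials): FCO/FCL scalars, average
#' and joint rewards, coordination fraction, MI colour/side with
#' surrogate significance, the DCR with its confidence interval, the
#' MI-plane strategy classification, the three action-time difference
#' tests, the visibility-following correlations, seamless-switch and
#' uncoordinated-class tallies. The result is JSON-serialisable and
#' deterministic given `config$seed`. Solo sessions
#' (`condition == "solo"`) get per-agent choice metrics only, with the
#' dyadic block flagged not applicable.
#'
#' @param session a `bos_session`.
#' @param config an [analysis_config()].
#' @return A nested list (class `bos_metrics`) that records the effective
#'   configuration under `$config`.
#' @export
analyze_session <- function(session, config = analysis_config()) {
  win <- last_n(session, config$last_n)
  has_at <- any(!is.na(win$trials$t_rel_A_ms) & !is.na(win$trials$t_rel_B_ms))
  bundle <- list(
    session = list(agents = session$agents, species = session$species,
                   condition = session$condition,
                   n_trials_total = n_trials(session),
                   n_trials_analyzed = n_trials(win),
                   short_session = isTRUE(win$meta$short_session)),
    choice = list(
      fco_A = fco(win, "A", config$w)$scalar,
      fco_B = fco(win, "B", config$w)$scalar,
      fcl_A = fcl(win, "A", config$w)$scalar,
      fcl_B = fcl(win, "B", config$w)$scalar,
      average_reward_A = average_reward(win, "A"),
      average_reward_B = average_reward(win, "B"),
      joint_reward = average_reward(win, "pair"),
      coordination_fraction = coordination_fraction(win)))
  if (identical(session$condition, "solo")) {
    bundle$dyadic <- list(applicable = FALSE)
    bundle$config <- strip_class(config)
    class(bundle) <- "bos_metrics"
    return(bundle)
  }
  cls <- classify_strategy(win, config)
  vc <- if (has_at)
    visibility_correlation(win, w = config$w, k = config$psee_k,
                           dt0 = config$psee_dt0, seed = config$seed)
    else NULL
  bundle$dyadic <- list(
    applicable = TRUE,
    mi_color = strip_class(cls$diagnostics$mi_color),
    mi_side = strip_class(cls$diagnostics$mi_side),
    dcr = strip_class(cls$diagnostics$dcr),
    classification = cls$label,
    expected_coordination = cls$diagnostics$expected_coordination,
    at_tests = if (has_at) at_tests(win) else list(applicable = FALSE),
    visibility = if (has_at) vc else list(applicable = FALSE),
    switches = {
      sw <- seamless_switches(win)
      list(n_switches = sw$n_switches, n_selfish = sw$n_selfish,
           n_benevolent = sw$n_benevolent,
           n_unattributed = sw$n_unattributed,
           ci_low = sw$ci_low, ci_high = sw$ci_high, verdict = sw$verdict)
    },
    uncoordinated = uncoordinated_classes(win))
  bundle$config <- strip_class(config)
  class(bundle) <- "bos_metrics"
  bundle
}

#' Serialise a metrics bundle to JSON
#'
#' Key order follows the bundle construction order and floating-point
#' values are written with six significant digits, so identical analyses
#' produce byte-identical files.
#'
#' @param bundle a `bos_metrics` from [analyze_session()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(bundle, path) {
  json <- jsonlite::toJSON(strip_class(unclass(bundle)), auto_unbox = TRUE,
                           digits = I(6), na = "null", null = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' MI-plane summary table over sessions
#'
#' One row per analysed session with the coordinates of the MI plane
#' (MI side, MI colour), the DCR and the classification - the tabular
#' counterpart of an MI-plane scatter.
#'
#' @param bundles named list of `bos_metrics` bundles.
#' @return data.frame with columns `session`, `mi_side`, `mi_color`,
#'   `mi_side_significant`, `mi_color_significant`, `dcr`,
#'   `dcr_significant`, `classification`.
#' @export
mi_plane_table <- function(bundles) {
  stopifnot(length(bundles) > 0)
  if (is.null(names(bundles)))
    names(bundles) <- paste0("session_", seq_along(bundles))
  rows <- lapply(names(bundles), function(nm) {
    b <- bundles[[nm]]
    dy <- b$dyadic
    data.frame(session = nm,
               mi_side = dy$mi_side$mi_bits,
               mi_color = dy$mi_color$mi_bits,
               mi_side_significant = dy$mi_side$significant,
               mi_color_significant = dy$mi_color$significant,
               dcr = dy$dcr$dcr, dcr_significant = dy$dcr$significant,
               classification = dy$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram table of per-trial action-time differences
#'
#' Bins the per-trial action-time differences `AT_A - AT_B` (default bin
#' size 50 ms) separately for each coordination mode, the tabular
#' counterpart of the AT-difference histograms.
#'
#' @param session a `bos_session` with timestamps.
#' @param bin_ms bin width in ms (default 50).
#' @return data.frame with columns `mode`, `bin_left`, `bin_right`,
#'   `count`.
#' @export
at_difference_histogram <- function(session, bin_ms = 50) {
  at <- session_action_times(session)
  dt <- at$at_A - at$at_B
  modes <- trial_modes(session)
  ok <- !is.na(dt)
  dt <- dt[ok]; modes <- modes[ok]
  if (!length(dt))
    return(data.frame(mode = character(0), bin_left = numeric(0),
                      bin_right = numeric(0), count = integer(0)))
  lo <- floor(min(dt) / bin_ms) * bin_ms
  hi <- ceiling(max(dt) / bin_ms) * bin_ms
  if (hi == lo) hi <- lo + bin_ms
  breaks <- seq(lo, hi, by = bin_ms)
  nb <- length(breaks) - 1L
  rows <- lapply(sort(unique(modes)), function(m) {
    bin <- pmin(findInterval(dt[modes == m], breaks,
                             rightmost.closed = TRUE), nb)
    data.frame(mode = m, bin_left = breaks[-length(breaks)],
               bin_right = breaks[-1L],
               count = tabulate(bin, nbins = nb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
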