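# Naive mutual information between binary choice series and Whittle
# surrogate significance.

#' Extract binary choice series from a session
#'
#' `color_series()` returns the physical colour each agent selected
#' (`"red"` is agent A's preferred colour, `"blue"` agent B's);
#' `side_series()` returns the objective side (`"L"`/`"R"`). Mutual
#' information is invariant under relabelling, so these encodings are
#' interchangeable with own/other codings for MI purposes.
#'
#' @param session a `bos_session`.
#' @param agent `"A"` or `"B"`.
#' @return Character vector with one symbol per trial.
#' @name choice_series
NULL

#' @rdname choice_series
#' @export
color_series <- function(session, agent) {
  ch <- session$trials[[paste0("choice_", agent)]]
  pref <- if (agent == "A") "red" else "blue"
  nonpref <- if (agent == "A") "blue" else "red"
  ifelse(ch == "own", pref, nonpref)
}

#' @rdname choice_series
#' @export
side_series <- function(session, agent) {
  session$trials[[paste0("side_", agent)]]
}

#' Naive mutual information of two discrete series (bits)
#'
#' Plug-in estimator: probabilities in the mutual-information sum are
#' replaced by relative frequencies of the observed symbols, with the
#' convention that empty cells (0 log 0) contribute zero. For binary series
#' the result lies in \[0, 1\] bits; it is symmetric in its arguments and
#' invariant under relabelling of either alphabet. Tiny negative values
#' arising from floating-point cancellation are clamped to zero.
#'
#' @param x,y equal-length vectors of discrete symbols.
#' @return Mutual information in bits.
#' @examples
#' naive_mi(rep(c("L", "R"), 100), rep(c("L", "R"), 100))  # 1 bit
#' naive_mi(rep("L", 200), rep(c("L", "R"), 100))          # 0 bits
#' @export
naive_mi <- function(x, y) {
  if (length(x) == 0L) stop("empty input series")
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  joint <- table(x, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  max(0, sum(terms[joint > 0]))
}

# Shannon entropy (bits) of a discrete sample.
sample_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Whittle surrogates of a discrete series
#'
#' Generates randomised series that preserve the first-order (Markov)
#' transition counts and the initial symbol of `x` exactly - and hence also
#' its marginal symbol counts. Surrogates are drawn uniformly from the set
#' of admissible sequences: the run structure of a binary sequence with
#' fixed transition counts and start symbol is fixed up to the lengths of
#' its runs, so a uniform draw of the two run-length compositions (symbol
#' count split over the fixed number of runs of that symbol) yields an
#' exact uniform sample without rejection. A constant series is its own
#' unique surrogate.
#'
#' @param x vector of symbols (at most two distinct values).
#' @param n_surrogates number of surrogates (>= 1).
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream (used internally by [mi_significance()]).
#' @return A matrix with `n_surrogates` rows; each row is one surrogate
#'   series over the same alphabet as `x`.
#' @export
whittle_surrogates <- function(x, n_surrogates, seed = 1L) {
  if (length(x) < 3L) stop("series too short (need length >= 3)")
  if (n_surrogates < 1L) stop("'n_surrogates' must be >= 1")
  symbols <- unique(x)
  if (length(symbols) > 2L)
    stop("only binary series are supported")
  local_seed(seed)
  out <- matrix(x[1L], nrow = n_surrogates, ncol = length(x))
  if (length(symbols) == 1L) return(out)
  r <- rle(as.vector(x))
  s1 <- r$values[1L]
  s2 <- setdiff(symbols, s1)
  r1 <- sum(r$values == s1)   # number of runs of the start symbol
  r2 <- sum(r$values == s2)
  n1 <- sum(x == s1)
  n2 <- sum(x == s2)
  k <- length(r$values)
  for (j in seq_len(n_surrogates)) {
    len1 <- random_composition(n1, r1)
    len2 <- random_composition(n2, r2)
    lengths <- integer(k)
    lengths[seq(1L, k, by = 2L)] <- len1
    if (r2 > 0) lengths[seq(2L, k, by = 2L)] <- len2
    values <- rep(c(s1, s2), length.out = k)
    out[j, ] <- rep(values, lengths)
  }
  out
}

# Uniform composition of n into k positive parts.
random_composition <- function(n, k) {
  if (k == 0L) return(integer(0))
  if (k == 1L) return(n)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  diff(c(0L, cuts, n))
}

# Fast MI (bits) between paired rows of two 0/1 matrices.
mi_binary_rows <- function(xs, ys) {
  n <- ncol(xs)
  n11 <- rowSums(xs * ys)
  n10 <- rowSums(xs) - n11
  n01 <- rowSums(ys) - n11
  n00 <- n - n11 - n10 - n01
  term <- function(nxy, nx, ny) {
    t <- numeric(length(nxy))
    pos <- nxy > 0
    t[pos] <- nxy[pos] / n * log2(nxy[pos] * n / (nx[pos] * ny[pos]))
    t
  }
  nx1 <- n11 + n10; nx0 <- n01 + n00
  ny1 <- n11 + n01; ny0 <- n10 + n00
  pmax(0, term(n11, nx1, ny1) + term(n10, nx1, ny0) +
         term(n01, nx0, ny1) + term(n00, nx0, ny0))
}

#' Surrogate-based significance of mutual information
#'
#' Tests whether the mutual information between two binary series exceeds
#' what their individual first-order dynamics alone can produce. The null
#' distribution is obtained by drawing `n_surrogates` independent Whittle
#' surrogates of each series (independence between the surrogate pair
#' destroys any cross-series dependence while preserving each series'
#' autocorrelation structure) and computing the MI of each surrogate pair;
#' the threshold is the `1 - alpha` empirical quantile of those values.
#'
#' The observed MI is significant when it strictly exceeds the threshold.
#' One degenerate case needs care: if the two series are an exact
#' deterministic bijection of each other (MI equal to both marginal
#' entropies) and carry any uncertainty at all (MI > 0), the surrogate set
#' can itself be fully determined by the transition counts (e.g. strict
#' lockstep alternation), so every surrogate pair reproduces the observed
#' MI and strict exceedance cannot fire even though the dependence is
#' perfect; such in-sample bijections are reported as significant. Constant
#' series (MI = 0) remain non-significant.
#'
#' @param x,y equal-length binary series.
#' @param alpha significance level (default 0.01, one-sided).
#' @param n_surrogates number of surrogate pairs (default 1000).
#' @param seed integer seed.
#' @return An object of class `bos_mi_result`: list with `mi_bits`,
#'   `surrogate_threshold_bits`, `n_surrogates`, `alpha`, `significant`.
#' @export
mi_significance <- function(x, y, alpha = 0.01, n_surrogates = 1000L,
                            seed = 1L) {
  if (length(x) != length(y)) stop("series lengths differ")
  mi <- naive_mi(x, y)
  local_seed(seed)
  xs <- whittle_surrogates(x, n_surrogates, seed = NULL)
  ys <- whittle_surrogates(y, n_surrogates, seed = NULL)
  xb <- matrix(as.integer(xs == x[1L]), nrow = n_surrogates)
  yb <- matrix(as.integer(ys == y[1L]), nrow = n_surrogates)
  mis <- mi_binary_rows(xb, yb)
  thr <- sort(mis)[ceiling((1 - alpha) * n_surrogates)]
  deterministic <- mi > 0 &&
    abs(mi - sample_entropy(x)) < 1e-12 &&
    abs(mi - sample_entropy(y)) < 1e-12
  structure(list(mi_bits = mi, surrogate_threshold_bits = thr,
                 n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 significant = (mi > thr) || deterministic),
            class = "bos_mi_result")
}

#' @export
print.bos_mi_result <- function(x, ...) {
  cat(sprintf("<bos_mi_result> MI = %.4f bits, threshold = %.4f (alpha = %g, %d surrogates): %s\n",
              x$mi_bits, x$surrogate_threshold_bits, x$alpha, x$n_surrogates,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
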