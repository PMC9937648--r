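# Independent oracles: deliberately naive reimplementations used only to
# check the package's fast paths.

# Brute-force mutual information (bits) by explicit joint counting.
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (vx in unique(x)) for (vy in unique(y)) {
    pxy <- sum(x == vx & y == vy) / n
    if (pxy > 0) {
      px <- sum(x == vx) / n
      py <- sum(y == vy) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# Textbook Welch/Satterthwaite two-sample t-test.
oracle_welch <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  v1 <- var(g1); v2 <- var(g2)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# First-order transition counts of a binary vector, plus start symbol.
transition_signature <- function(x) {
  pairs <- paste(x[-length(x)], x[-1L], sep = ">")
  sig <- table(factor(pairs, levels = c("0>0", "0>1", "1>0", "1>1")))
  c(start = x[1L], as.vector(sig))
}

# All binary sequences of a given length, as a matrix of 0/1 rows.
all_binary_sequences <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  dimnames(m) <- NULL
  m
}

# A pair of 0/1 series realising the joint contingency counts
# (n00, n01, n10, n11); any arrangement works since MI only depends on
# the joint counts.
series_from_counts <- function(n00, n01, n10, n11) {
  x <- c(rep(0, n00 + n01), rep(1, n10 + n11))
  y <- c(rep(0, n00), rep(1, n01), rep(0, n10), rep(1, n11))
  list(x = x, y = y)
}
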