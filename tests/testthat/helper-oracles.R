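# Independent oracles used across the suite. Each is a deliberately naive
# reference implementation, kept separate from the package's own code paths.

# Exhaustive optimal k-modes cost by dynamic programming over subsets:
# cost of a cluster = sum over attributes of (size - max category count),
# i.e. the matching dissimilarity of members to the attribute-wise mode.
exhaustive_kmodes_cost <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 12, k %in% 1:3)
  ncat <- max(x) + 1L
  full <- bitwShiftL(1L, n) - 1L
  bits <- bitwShiftL(1L, 0:(n - 1))
  cost1 <- vapply(seq_len(full), function(m) {
    rows <- which(bitwAnd(m, bits) != 0)
    sub <- x[rows, , drop = FALSE]
    sum(apply(sub, 2, function(col) {
      length(col) - max(tabulate(col + 1L, nbins = ncat))
    }))
  }, numeric(1))
  if (k == 1) {
    return(cost1[full])
  }
  cost2 <- rep(Inf, full)
  for (m in seq_len(full)) {
    s <- bitwAnd(m - 1L, m)
    while (s > 0L) {
      cand <- cost1[s] + cost1[m - s]
      if (cand < cost2[m]) cost2[m] <- cand
      s <- bitwAnd(s - 1L, m)
    }
  }
  if (k == 2) {
    return(cost2[full])
  }
  best <- Inf
  s <- bitwAnd(full - 1L, full)
  while (s > 0L) {
    rest <- full - s
    if (rest > 0L && is.finite(cost2[s])) {
      cand <- cost1[rest] + cost2[s]
      if (cand < best) best <- cand
    }
    s <- bitwAnd(s - 1L, full)
  }
  best
}

# Textbook Pearson chi-square on a counts matrix.
chisq_oracle <- function(m) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - expected)^2 / expected)
}

# Brute-force consecutive-day counter: for each date, walk backwards while
# the previous calendar day is present.
run_length_oracle <- function(dates) {
  d <- sort(unique(as.integer(dates)))
  vapply(d, function(day) {
    len <- 1L
    while ((day - len) %in% d) len <- len + 1L
    len
  }, integer(1))
}

# Random valid fuzzy-domain parameters. The medium triangle must clear both
# shoulders, so the median is drawn inside the feasible band.
random_domain_params <- function() {
  m <- runif(1, -50, 50)
  M <- m + runif(1, 5, 100)
  # h close to the (M-m)/6 bound leaves no room for the median band below
  h <- runif(1, 0.05, 0.8) * (M - m) / 6
  third <- (M - m) / 6
  lo <- m + third + 2 * h
  hi <- M - third - 2 * h
  med <- runif(1, lo + 0.02 * (M - m), hi - 0.02 * (M - m))
  list(m = m, M = M, median_t = med, h = h)
}

random_pattern_matrix <- function(n, p, ncat = 6) {
  matrix(sample(0:(ncat - 1), n * p, replace = TRUE), nrow = n)
}
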