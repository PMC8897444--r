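# Independent oracles used by the tests; deliberately brute-force and
# separate from the implementation paths they check.

# direct pmf summation for the three hypothesis p-values
oracle_p_error <- function(E, C, rate = 1e-3) {
  if (E == 0) return(1)
  sum(choose(C, E:C) * rate^(E:C) * (1 - rate)^(C - (E:C)))
}
oracle_p_hetero <- function(E, C, prior = 1e-4, f = 0.5) {
  prior * sum(choose(C, 0:E) * f^(0:E) * (1 - f)^(C - (0:E)))
}
oracle_p_homo <- function(E, C, prior = 1e-8) {
  # lower-tail sum with success probability 1: only the j = C term survives
  if (E == C) prior else 0
}

# O(n^2) transitive-closure clustering oracle: iterate label propagation
# over the pairwise <= maxGap adjacency until a fixed point
oracle_clusters <- function(pos, maxGap = 100) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= maxGap
  comp <- seq_len(n)
  repeat {
    newComp <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(newComp, comp)) break
    comp <- newComp
  }
  match(comp, unique(comp))
}

# textbook step-up procedures on a raw p-value vector
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
oracle_by <- function(p) {
  n <- length(p)
  cm <- sum(1 / seq_len(n))
  o <- order(p)
  adj <- p[o] * n * cm / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# two-sided conditional exact test on a 2x2 table by enumeration over all
# tables with the observed margins, summing probabilities <= observed
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
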