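# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the code paths of the implementation: the
# Fisher oracle enumerates the hypergeometric distribution directly, the
# signed-rank oracle enumerates sign assignments, and the Friedman oracle
# enumerates within-block permutations with a hand-written statistic.

fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  pr <- stats::dhyper(x, c1, n - c1, r1)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

signed_rank_oracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs); p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Friedman statistic written out from the rank definition (mid-ranks with
# tie correction), independent of stats::friedman.test.
friedman_stat_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  ties <- apply(r, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) /
    (n * k * (k + 1) - sum(ties) / (k - 1))
}

# Exact permutation p-value by enumerating all (k!)^n within-block
# permutations of the observed values.
friedman_p_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  perms <- asplit(permute_all(k), 1)
  grid <- expand.grid(rep(list(seq_along(perms)), n))
  stat_obs <- friedman_stat_oracle(m)
  hits <- 0
  mm <- m
  for (g in seq_len(nrow(grid))) {
    for (b in seq_len(n)) mm[b, ] <- m[b, perms[[grid[g, b]]]]
    if (friedman_stat_oracle(mm) >= stat_obs - 1e-12) hits <- hits + 1
  }
  hits / nrow(grid)
}

# All k! permutations as rows of a matrix (iterative heap-like build).
permute_all <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permute_all(k - 1)
  out <- NULL
  for (pos in 0:(k - 1)) {
    blk <- t(apply(sub, 1, function(s) append(s, k, after = pos)))
    out <- rbind(out, blk)
  }
  out
}
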