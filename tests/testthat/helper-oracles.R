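# Independent brute-force oracles used to validate the implementation.
# They deliberately avoid qbeta: bounds are located on a 1e-6 grid of
# probabilities by direct evaluation of the binomial tail. The tail
# probabilities are monotone in the success probability, so a binary search
# over the grid returns exactly the same grid point a full scan would.

# smallest u on the grid with P(Binomial(denom, u) <= k) <= level
grid_upper_oracle <- function(k, denom, level, step = 1e-6) {
  n_grid <- as.integer(round(1 / step))
  f <- function(i) pbinom(k, denom, i * step) # nonincreasing in i
  if (f(n_grid) > level) return(1) # no grid point qualifies (e.g. k = denom)
  lo <- 0L; hi <- n_grid
  while (lo < hi) { # invariant: f(hi) <= level < f(lo) (or lo qualifies)
    mid <- (lo + hi) %/% 2L
    if (f(mid) <= level) hi <- mid else lo <- mid + 1L
  }
  hi * step
}

# largest l on the grid with P(Binomial(denom, l) >= j) <= level
grid_lower_oracle <- function(j, denom, level, step = 1e-6) {
  n_grid <- as.integer(round(1 / step))
  g <- function(i) 1 - pbinom(j - 1, denom, i * step) # nondecreasing in i
  if (j == 0 || g(0L) > level) return(0)
  lo <- 0L; hi <- n_grid
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (g(mid) <= level) lo <- mid else hi <- mid - 1L
  }
  lo * step
}

# q-values recomputed by definition: for each gene, minimum over all
# thresholds at least as permissive (score <=) of pi0 * (k/r) / (j/m)
brute_force_qvalues <- function(scores, pool, pi0) {
  m <- length(scores)
  raw <- vapply(scores, function(t) {
    k <- sum(pool >= t)
    j <- sum(scores >= t)
    pi0 * (k / length(pool)) / (j / m)
  }, numeric(1))
  q <- vapply(seq_len(m), function(i) {
    min(raw[scores <= scores[i]])
  }, numeric(1))
  pmin(q, 1)
}
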