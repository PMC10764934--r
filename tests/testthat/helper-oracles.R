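# Independent oracles used to cross-check the implementation.

# Trajectory entropy by forward truncated enumeration. All trajectories from
# state i to first hitting j are expanded step by step; partial paths ending
# in the same state are aggregated exactly (sum of p and of p*log2(p) per
# state fully determine all future contributions), so the sum
# -sum_paths p log2 p is computed without the linear solve used by the
# implementation. Truncated when the un-hit mass drops below `tail`.
enumeration_trajectory_entropy <- function(p, i, j, tail = 1e-6,
                                           max_steps = 200000L) {
  k <- nrow(p)
  s_mass <- numeric(k); s_plogp <- numeric(k)
  s_mass[i] <- 1                       # the empty partial path at the start
  total <- 0
  for (step in seq_len(max_steps)) {
    n_mass <- numeric(k); n_plogp <- numeric(k)
    for (m in which(s_mass > 0)) {
      for (mp in seq_len(k)) {
        q <- p[m, mp]
        if (q == 0) next
        add_mass <- s_mass[m] * q
        add_plogp <- q * s_plogp[m] + add_mass * log2(q)
        if (mp == j) {                 # trajectory terminates at j
          total <- total - add_plogp
        } else {
          n_mass[mp] <- n_mass[mp] + add_mass
          n_plogp[mp] <- n_plogp[mp] + add_plogp
        }
      }
    }
    s_mass <- n_mass; s_plogp <- n_plogp
    if (sum(s_mass) < tail) break
  }
  total
}

# Brute-force Benjamini-Hochberg step-up from the defining formula.
bruteforce_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (rank_i in seq_len(m)) {
    js <- rank_i:m
    q[ord[rank_i]] <- min(1, min(p[ord[js]] * m / js))
  }
  q
}

# OLS by explicit normal equations; returns the t statistic of column `col`.
bruteforce_ols_t <- function(x, y, col) {
  xtx <- t(x) %*% x
  beta <- solve(xtx, t(x) %*% y)
  res <- y - x %*% beta
  df <- nrow(x) - ncol(x)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(xtx)[col, col])
  list(t = beta[col] / se, df = df)
}

# Mann-Whitney U by exhaustive pairwise comparison (ties count 1/2).
bruteforce_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
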