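# Brute-force enumeration oracles for the exact nonparametric tests,
# written independently of the package's implementations.

# two-sided doubled-tail signed-rank p over all 2^m sign patterns
oracle_signed_rank_p <- function(pre, post) {
  d <- (post - pre)[post != pre]
  m <- length(d)
  if (!m) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    sum(rk[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1))
  out <- list()
  for (sub in combinat_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos)
    }
  }
  out
}

# Friedman exact p: enumerate every assignment of each subject's values to
# the conditions, recomputing the tie-corrected statistic from scratch
oracle_friedman_p <- function(y) {
  s <- nrow(y); k <- ncol(y)
  stat_of <- function(m) {
    r <- t(apply(m, 1, rank))
    ties <- sum(apply(r, 1, function(row) {
      tb <- table(row); sum(tb^3 - tb)
    }))
    C <- 1 - ties / (s * (k^3 - k))
    num <- 12 * sum((colSums(r) - s * (k + 1) / 2)^2)
    if (C <= 0) return(if (num == 0) 0 else NA_real_)
    num / (s * k * (k + 1) * C)
  }
  obs <- stat_of(y)
  perms <- as.matrix(expand.grid(rep(list(1:factorial(k)), s)))
  all_orders <- matrix(unlist(combinat_perms(k)), ncol = k, byrow = TRUE)
  count <- 0L
  for (p in seq_len(nrow(perms))) {
    m <- y
    for (i in seq_len(s)) m[i, ] <- y[i, all_orders[perms[p, i], ]]
    if (stat_of(m) >= obs - 1e-9) count <- count + 1L
  }
  count / nrow(perms)
}
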