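# Independent brute-force oracles used to pin expected values. These are
# deliberately written from first principles (explicit enumeration, normal
# equations) and share no code with the package internals they check.

# all permutations of 1..n, built iteratively by insertion
oracle_permutations <- function(n) {
  rows <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    out <- vector("list", k * nrow(rows))
    idx <- 1L
    for (r in seq_len(nrow(rows))) {
      for (pos in seq_len(k)) {
        out[[idx]] <- append(rows[r, ], k, after = pos - 1L)
        idx <- idx + 1L
      }
    }
    rows <- do.call(rbind, out)
  }
  rows
}

# Spearman rho via explicit products of centred average ranks
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# two-sided exact permutation p: fraction of all n! orderings of y with
# |rho| at least the observed
oracle_spearman_p <- function(x, y) {
  obs <- abs(oracle_spearman_rho(x, y))
  perms <- oracle_permutations(length(y))
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    if (abs(oracle_spearman_rho(x, y[perms[r, ]])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / nrow(perms)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  p_lo <- mean(w <= wobs + 1e-12)
  p_hi <- mean(w >= wobs - 1e-12)
  min(1, 2 * min(p_lo, p_hi))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mannwhitney_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uobs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  u <- apply(sets, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u <= uobs + 1e-12), mean(u >= uobs - 1e-12)))
}

# least squares by explicitly solving the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}
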