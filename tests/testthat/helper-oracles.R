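# Independent brute-force oracles for the exact nonparametric tests. These
# deliberately avoid rank()/psignrank()/pwilcox() so they share no code path
# with the implementation they check.

# average ranks by explicit sort-and-scan
slow_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- slow_ranks(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
enum_mann_whitney_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 + n2 <= 12)
  pooled <- c(a, b)
  r <- slow_ranks(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2L, u_of)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# independent paired rank-biserial: signed-rank sums via slow_ranks
oracle_rank_biserial <- function(x, y) {
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  if (length(d) == 0) return(0)
  r <- slow_ranks(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

# smallest absolute angular difference in degrees
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
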