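# Independent brute-force oracles, coded deliberately naively and separately
# from the package's implementation paths.

# Gini via the mean-absolute-difference definition:
# G = sum_ij |x_i - x_j| / (2 n sum(x)).
oracle_gini <- function(x) {
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) total <- total + abs(x[i] - x[j])
  total / (2 * n * sum(x))
}

# Tau by direct looping over the definition.
oracle_tau <- function(x) {
  m <- max(x)
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (1 - x[i] / m)
  acc / (length(x) - 1)
}

# TMM factor of column j against reference column r, spelled out step by
# step with order()-based trimming (the package path uses rank()-based
# boundaries; both implement the same double-trim rule).
oracle_tmm_factor <- function(mat, j, r) {
  obs <- mat[, j]; ref <- mat[, r]
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * 0.30) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  rank_m <- rank(M); rank_a <- rank(A)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (rank_m[i] >= lo_m && rank_m[i] <= hi_m &&
        rank_a[i] >= lo_a && rank_a[i] <= hi_a) {
      num <- num + M[i] / w[i]
      den <- den + 1 / w[i]
    }
  }
  2^(num / den)
}

# Exact Mann-Whitney by exhaustive enumeration of all rank arrangements
# (tie-free data, group sizes small). U counts pairs where a > b.
oracle_mwu <- function(a, b, alternative) {
  stat_u <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi)
    u
  }
  u_obs <- stat_u(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2, function(idx) stat_u(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  p <- switch(alternative,
              less = p_le,
              greater = p_ge,
              two.sided = min(1, 2 * (if (u_obs > n1 * length(b) / 2) p_ge else p_le)))
  list(U = u_obs, p = p)
}

# Upper-tail hypergeometric by combinatorial arithmetic.
oracle_hyper <- function(overlap, n_marked, n_drawn, universe) {
  total <- 0
  for (j in overlap:min(n_marked, n_drawn))
    total <- total + choose(n_marked, j) * choose(universe - n_marked, n_drawn - j)
  total / choose(universe, n_drawn)
}
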