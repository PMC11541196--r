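# Weighted delete-one-block jackknife for ratio-of-sums statistics.
#
# All f-statistics in this package are ratios of per-site sums
# (for f2/f3/f4 the denominator is the used-site count, for FST a proper
# per-site denominator). The standard error uses the weighted delete-mj
# jackknife of Busing et al. (1999), with block weights equal to the number
# of sites each block contributes.

# num, den: per-site numerator/denominator values (already masked to used
# sites); block: block index per used site; g_total: total number of blocks
# in the partition (blocks contributing no sites are dropped).
block_jackknife_ratio <- function(num, den, block) {
  stopifnot(length(num) == length(den), length(num) == length(block))
  num_b <- rowsum(num, block)
  den_b <- rowsum(den, block)
  m_b <- as.vector(rowsum(rep(1, length(block)), block))
  keep <- m_b > 0
  num_b <- num_b[keep]
  den_b <- den_b[keep]
  m_b <- m_b[keep]
  g <- length(m_b)
  N <- sum(num_b)
  D <- sum(den_b)
  est <- N / D
  if (g < 2) {
    return(list(estimate = est, se = NA_real_, n_blocks = g,
                n_sites = sum(m_b), loo = rep(est, g), weights = m_b))
  }
  loo <- (N - num_b) / (D - den_b)
  n <- sum(m_b)
  h <- n / m_b
  theta_j <- g * est - sum((1 - m_b / n) * loo)
  tau <- h * est - (h - 1) * loo
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(estimate = est, se = sqrt(var_j), n_blocks = g, n_sites = n,
       loo = loo, weights = m_b)
}

# Unweighted delete-one jackknife covariance of a vector statistic from its
# leave-one-block-out replicates (rows = blocks). Used for the covariance of
# vectorized f4 systems, where blocks are of near-equal genetic size.
jackknife_covariance <- function(loo) {
  loo <- as.matrix(loo)
  g <- nrow(loo)
  centered <- sweep(loo, 2, colMeans(loo))
  crossprod(centered) * (g - 1) / g
}

# Delete-one jackknife SE of each component of a vector statistic.
jackknife_se_vec <- function(loo) {
  g <- nrow(as.matrix(loo))
  sqrt(diag(jackknife_covariance(loo)))  # already includes (g-1)/g scaling
}

# Solve Q^{-1} b with a logged ridge fallback when Q is numerically singular.
solve_psd <- function(Q, b, ridge = 1e-6) {
  ch <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(ch)) {
    lambda <- ridge * mean(diag(Q))
    message("covariance numerically singular; ridge-regularizing with lambda = ",
            format(lambda))
    ch <- chol(Q + diag(lambda, nrow(Q)))
  }
  backsolve(ch, forwardsolve(t(ch), b))
}
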