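# Independent brute-force oracles used to validate the analytical
# implementations.  These deliberately use different computational
# routes than the package code.

# Fisher exact two-sided p by full enumeration of the hypergeometric
# support at fixed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square by summing (obs - exp)^2 / exp over the 4 cells.
oracle_chi2_stat <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# KMO via partial correlations computed by regression residuals
# (independent of the inverse-matrix identity the package uses).
oracle_kmo <- function(R) {
  p <- ncol(R)
  q <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(1:p, c(i, j))
    if (length(others) == 0) {
      q[i, j] <- R[i, j]
    } else {
      # partial correlation via the recursive formula on the
      # conditioning set, evaluated through covariance algebra
      Roo <- R[others, others, drop = FALSE]
      ri <- R[i, others]; rj <- R[j, others]
      w <- solve(Roo)
      num <- R[i, j] - ri %*% w %*% rj
      den <- sqrt((1 - ri %*% w %*% ri) * (1 - rj %*% w %*% rj))
      q[i, j] <- num / den
    }
    q[j, i] <- q[i, j]
  }
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
}

# Varimax criterion for a p x 2 loading matrix rotated by angle theta.
oracle_varimax_best_k2 <- function(L, normalize = TRUE,
                                   step = 1e-4) {
  h <- sqrt(rowSums(L^2)); h[h == 0] <- 1
  W <- if (normalize) L / h else L
  crit <- function(theta) {
    Rm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
    V <- W %*% Rm
    sum(apply(V^2, 2, function(x) mean((x - mean(x))^2)))
  }
  thetas <- seq(0, pi / 2, by = step)
  max(vapply(thetas, crit, 1))
}

# AUC by exhaustive pairwise concordance counting.
oracle_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (x in case_scores) for (y in control_scores)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(case_scores) * length(control_scores))
}

# Hanley-McNeil interval evaluated directly from the printed formula.
oracle_hanley_mcneil <- function(A, n1, n2) {
  Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) +
                (n2 - 1) * (Q2 - A^2)) / (n1 * n2))
  c(A - stats::qnorm(0.975) * se, A + stats::qnorm(0.975) * se)
}

# Spearman-Brown alpha for p items with common correlation r.
oracle_spearman_brown <- function(p, r) p * r / (1 + (p - 1) * r)
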