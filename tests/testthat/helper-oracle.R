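# Independent oracles, deliberately naive implementations.

# -2 REML log-likelihood by dense matrix algebra at given (tau2, sigma2).
naive_reml_m2ll <- function(y, X, group, tau2, sigma2) {
  Z <- model.matrix(~ 0 + factor(group))
  V <- sigma2 * diag(length(y)) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  as.numeric(determinant(V)$modulus + determinant(A)$modulus +
               t(r) %*% Vi %*% r + (n - p) * log(2 * pi))
}

# Dense grid search over (tau2, sigma2), refined in stages.  The grid is
# laid out along (tau2/sigma2, sigma2) so the criterion's curved ridge in
# the original axes becomes axis-aligned; every candidate is still scored
# by the naive dense evaluator at its (tau2, sigma2) pair, and the
# tau2 = 0 boundary is kept in every stage.  Returns the best grid point,
# its criterion, and the GLS condition-effect refit there.
grid_reml_oracle <- function(y, X, group, n1 = 41, n2 = 17) {
  vy <- var(y)
  best <- c(NA, NA, Inf)   # (lambda, sigma2, crit)
  evalg <- function(lams, s2s) {
    for (lam in lams) for (s2 in s2s) {
      v <- naive_reml_m2ll(y, X, group, lam * s2, s2)
      if (v < best[3]) best <<- c(lam, s2, v)
    }
  }
  evalg(c(0, exp(seq(log(1e-6), log(1e3), length.out = n1))),
        exp(seq(log(vy / 100), log(4 * vy), length.out = 25)))
  for (stage in 1:4) {
    l0 <- best[1]; s0 <- best[2]
    span <- 0.7^stage
    lams <- if (l0 == 0) c(0, exp(seq(log(1e-8), log(1e-3),
                                      length.out = n2)))
            else c(0, l0 * exp(seq(-span, span, length.out = n2)))
    evalg(lams, s0 * exp(seq(-span, span, length.out = n2)))
  }
  # polish by nested 1D minimization (outer: log variance ratio, inner:
  # log sigma2), still scoring with the naive dense evaluator
  inner <- function(lam) {
    o <- optimize(function(ls) naive_reml_m2ll(y, X, group, lam * exp(ls),
                                               exp(ls)),
                  interval = log(best[2]) + c(-2, 2), tol = 1e-12)
    o
  }
  if (best[1] > 0) {
    op <- optimize(function(ll) inner(exp(ll))$objective,
                   interval = log(best[1]) + c(-1.5, 1.5), tol = 1e-11)
    lam <- exp(op$minimum)
    oi <- inner(lam)
    if (oi$objective < best[3]) best <- c(lam, exp(oi$minimum), oi$objective)
  }
  o0 <- inner(0)
  if (o0$objective <= best[3]) best <- c(0, exp(o0$minimum), o0$objective)
  tau2 <- best[1] * best[2]
  Z <- model.matrix(~ 0 + factor(group))
  V <- best[2] * diag(length(y)) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(tau2 = tau2, sigma2 = best[2], crit = best[3],
       effect = beta[2, 1])
}

# CDF of a sum of iid F(1, nu) variates by discretized convolution
# (equal-mass quantile representation of all but the last summand).
fsum_cdf_oracle <- function(w, k, nu, n_grid = 400) {
  probs <- (seq_len(n_grid) - 0.5) / n_grid
  q <- qf(probs, 1, nu)
  if (k == 1) return(pf(w, 1, nu))
  sums <- q
  for (i in seq_len(k - 2)) sums <- as.vector(outer(sums, q, "+"))
  mean(pf(w - sums, 1, nu))
}
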