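# Analytic oracles used across tests.

# Conjugate Bayesian linear regression: y = X theta + e, e ~ N(0, 1/w)
# with known per-observation precision w and prior N(m0, C0).
# Returns posterior mean/covariance and the exact log evidence.
conjugate_linear <- function(y, X, w, m0, C0) {
  P0 <- solve(C0)
  w <- rep(w, length.out = length(y))
  H <- crossprod(X * w, X) + P0
  Cp <- solve(H)
  mu <- drop(Cp %*% (crossprod(X, w * y) + P0 %*% m0))
  n <- length(y)
  log_ev <- -n / 2 * log(2 * pi) + 0.5 * sum(log(w)) -
    0.5 * determinant(C0)$modulus - 0.5 * determinant(H)$modulus -
    0.5 * (sum(w * y ^ 2) + drop(t(m0) %*% P0 %*% m0) -
             drop(t(mu) %*% H %*% mu))
  list(mean = mu, cov = Cp, log_evidence = as.numeric(log_ev))
}

# deterministic threshold observer: always correct at/above t, wrong below
step_observer_correct <- function(tmr, t) tmr >= t

# random linear-Gaussian test instance
make_linear_instance <- function(n = 40, p = 5, seed = 1, sigma = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  theta <- rnorm(p)
  y <- drop(X %*% theta) + sigma * rnorm(n)
  list(X = X, y = y, theta = theta, w = 1 / sigma ^ 2)
}
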