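# fabricate a small set of subject posteriors over named parameters
fake_posteriors <- function(means, sds = 0.1) {
  lapply(seq_len(nrow(means)), function(s)
    gaussian_belief(mean = means[s, ],
                    cov = diag(rep(sds, length.out = ncol(means)) ^ 2,
                               ncol(means))))
}

test_that("PEB with identical subjects and intercept design returns the shared mean", {
  nm <- c("B.difficulty.a.self", "B.difficulty.b.self")
  mu <- c(-0.4, 0.2)
  means <- matrix(rep(mu, each = 4), 4, dimnames = list(NULL, nm))
  colnames(means) <- nm
  posts <- fake_posteriors(means, sds = 0.05)
  peb <- peb_fit(posts, X = matrix(1, 4, 1), beta_prior_var = 1e6,
                 gamma = 0)
  expect_lt(max(abs(peb$beta$mean - mu)), 1e-6)
})

test_that("PEB equals the precision-weighted least-squares oracle", {
  nm <- c("B.difficulty.a.self", "B.difficulty.b.self")
  m1 <- c(-0.5, 0.1); m2 <- c(-0.2, 0.4)
  C1 <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  C2 <- matrix(c(0.16, -0.02, -0.02, 0.05), 2)
  posts <- list(gaussian_belief(stats::setNames(m1, nm), C1),
                gaussian_belief(stats::setNames(m2, nm), C2))
  peb <- peb_fit(posts, X = matrix(1, 2, 1), beta_prior_var = 1e8,
                 gamma = 0)
  W1 <- solve(C1); W2 <- solve(C2)
  oracle <- solve(W1 + W2, W1 %*% m1 + W2 %*% m2)
  expect_lt(max(abs(peb$beta$mean - drop(oracle))), 1e-6)
})

test_that("PEB is invariant to subject permutation and rejects bad designs", {
  set.seed(1)
  nm <- paste0("B.difficulty.", letters[1:3], ".self")
  means <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, nm))
  colnames(means) <- nm
  posts <- fake_posteriors(means)
  X <- cbind(1, rnorm(5))
  peb1 <- peb_fit(posts, X)
  perm <- c(3, 1, 5, 2, 4)
  peb2 <- peb_fit(posts[perm], X[perm, ])
  expect_lt(max(abs(peb1$beta$mean - peb2$beta$mean)), 1e-6)
  expect_error(peb_fit(posts, cbind(1, rep(2, 5))), "rank")
  expect_error(peb_fit(posts[1], matrix(1, 1, 1)), "2 subjects")
})

test_that("Bayesian model reduction: identity, irrelevant parameters, refit oracle", {
  inst <- make_linear_instance(n = 50, p = 6, seed = 4, sigma = 0.6)
  m0 <- rep(0, 6)
  C_full <- diag(0.8, 6)
  full <- conjugate_linear(inst$y, inst$X, inst$w, m0, C_full)
  full_prior <- gaussian_belief(m0, C_full)
  full_post <- gaussian_belief(full$mean, full$cov,
                               free_energy = full$log_evidence)

  # identity reduction
  ident <- bayesian_model_reduction(full_prior, full_post, full_prior)
  expect_lt(abs(ident$delta_F), 1e-10)
  expect_lt(max(abs(ident$posterior$mean - full$mean)), 1e-10)

  # refit oracle: switch off parameters 5 and 6
  C_red <- C_full
  C_red[5, 5] <- C_red[6, 6] <- 1e-8
  red <- bayesian_model_reduction(full_prior, full_post,
                                  gaussian_belief(m0, C_red))
  refit <- conjugate_linear(inst$y, inst$X, inst$w, m0, C_red)
  expect_lt(abs(red$delta_F - (refit$log_evidence - full$log_evidence)),
            1e-6)
  expect_lt(max(abs(red$posterior$mean - refit$mean)), 1e-6)
  expect_lt(max(abs(as.matrix(red$posterior$cov) - refit$cov)), 1e-6)

  # switching off a parameter the data do not inform barely moves F
  Xz <- cbind(inst$X[, 1:5], 0)
  fullz <- conjugate_linear(inst$y, Xz, inst$w, m0, C_full)
  redz <- bayesian_model_reduction(
    full_prior, gaussian_belief(fullz$mean, fullz$cov,
                                free_energy = fullz$log_evidence),
    gaussian_belief(m0, `[<-`(C_full, 6, 6, 1e-8)))
  expect_lt(abs(redz$delta_F), 0.1)
})

test_that("greedy search prunes null effects and scores exactly 256 models", {
  # sharp posterior: parameters 1-2 strongly nonzero, the rest at zero
  K <- 12
  nm <- paste0("mean:B.difficulty.p", seq_len(K))
  prior <- gaussian_belief(stats::setNames(rep(0, K), nm), diag(1 / 4, K))
  post_mean <- c(-0.5, -0.45, rep(0, K - 2))
  post <- gaussian_belief(stats::setNames(post_mean, nm),
                          diag(0.003, K), free_energy = 0)
  peb <- structure(list(beta = post, prior = prior,
                        params = nm, covariates = "mean"),
                   class = "peb_model")
  ms <- greedy_search(peb)
  expect_length(ms$models, 256)
  expect_true(all(!ms$terminal_mask[3:K]))
  expect_true(all(ms$terminal_mask[1:2]))
  best <- ms$models[[which.max(vapply(ms$models, `[[`, 0, "free_energy"))]]
  expect_true(all(best$mask[1:2]))
  expect_true(all(!best$mask[3:K]))

  # all-zero truth: the null model sits among the top models
  post0 <- gaussian_belief(stats::setNames(rep(0, K), nm),
                           diag(0.003, K), free_energy = 0)
  peb0 <- structure(list(beta = post0, prior = prior,
                         params = nm, covariates = "mean"),
                    class = "peb_model")
  ms0 <- greedy_search(peb0)
  Fs <- vapply(ms0$models, `[[`, 0, "free_energy")
  null_idx <- which(vapply(ms0$models, function(m) !any(m$mask), TRUE))
  expect_gte(Fs[null_idx], max(Fs) - 1e-6)

  # fewer than 8 candidates: enumerate 2^k instead
  expect_message(ms3 <- greedy_search(peb, candidates = 1:3), "fewer than")
  expect_length(ms3$models, 8)
})

test_that("model averaging weights, moments and posterior probabilities", {
  K <- 12
  nm <- paste0("mean:B.difficulty.p", seq_len(K))
  prior <- gaussian_belief(stats::setNames(rep(0, K), nm), diag(1 / 4, K))
  post <- gaussian_belief(stats::setNames(c(-0.5, -0.45, rep(0, K - 2)),
                                          nm),
                          diag(0.003, K), free_energy = 0)
  peb <- structure(list(beta = post, prior = prior, params = nm,
                        covariates = "mean"), class = "peb_model")
  bma <- bayesian_model_average(greedy_search(peb))
  expect_equal(sum(bma$weights), 1)
  expect_true(all(bma$pp >= 0 & bma$pp <= 1))
  expect_true(all(c(nm[1], nm[2]) %in% bma$retained))
  expect_false(any(nm[3:K] %in% bma$retained))
  expect_lt(max(abs(bma$mean[3:K])), 1e-3)
  expect_lt(abs(bma$mean[1] - (-0.5)), 0.05)

  # a single reduced model averages to itself with Pp = 1 on its
  # switched-on parameters
  rp <- gaussian_belief(prior$mean, `[<-`(as.matrix(prior$cov), cbind(3, 3),
                                          1e-8))
  one <- bayesian_model_reduction(prior, post, rp)
  one$mask <- c(TRUE, TRUE, FALSE, rep(TRUE, K - 3))
  b1 <- bayesian_model_average(list(one))
  expect_equal(unname(b1$mean), unname(one$posterior$mean))
  expect_equal(unname(b1$pp[1]), 1)

  # two models with equal free energy share the weight equally
  two <- bayesian_model_average(list(one, one))
  expect_equal(two$weights, c(0.5, 0.5))
  expect_error(bayesian_model_average(list()), "empty")
})
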