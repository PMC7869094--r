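test_that("variational Laplace matches the conjugate posterior and evidence on linear models", {
  inst <- make_linear_instance(n = 40, p = 5, seed = 1, sigma = 0.5)
  m0 <- rep(0, 5)
  C0 <- diag(0.5, 5)
  oracle <- conjugate_linear(inst$y, inst$X, inst$w, m0, C0)
  prior <- gaussian_belief(m0, C0)
  noise <- noise_model(groups = rep(1, 40), fixed_precision = inst$w)
  post <- variational_laplace(function(th) drop(inst$X %*% th), inst$y,
                              prior, noise)
  expect_lt(max(abs(post$mean - oracle$mean)), 1e-6)
  expect_lt(max(abs(post$cov - oracle$cov)), 1e-6)
  expect_lt(abs(post$free_energy - oracle$log_evidence), 1e-4)
})

test_that("free-energy differences reproduce analytic log Bayes factors", {
  inst <- make_linear_instance(n = 30, p = 4, seed = 2, sigma = 0.7)
  m0 <- rep(0, 4)
  noise <- noise_model(groups = rep(1, 30), fixed_precision = inst$w)
  f <- function(th) drop(inst$X %*% th)
  C_full <- diag(1, 4)
  C_red <- diag(c(1, 1, 1e-8, 1e-8))
  F_full <- variational_laplace(f, inst$y, gaussian_belief(m0, C_full),
                                noise)$free_energy
  F_red <- variational_laplace(f, inst$y, gaussian_belief(m0, C_red),
                               noise)$free_energy
  bf <- conjugate_linear(inst$y, inst$X, inst$w, m0, C_red)$log_evidence -
    conjugate_linear(inst$y, inst$X, inst$w, m0, C_full)$log_evidence
  expect_lt(abs((F_red - F_full) - bf), 1e-4)
})

test_that("noise hyperparameters are recovered when estimated", {
  set.seed(3)
  n <- 400
  X <- cbind(1, rnorm(n))
  theta <- c(2, -1)
  sigma <- 0.25
  y <- drop(X %*% theta) + sigma * rnorm(n)
  post <- variational_laplace(function(th) drop(X %*% th), y,
                              gaussian_belief(c(0, 0), diag(10, 2)),
                              noise_model(groups = rep(1, n)))
  expect_lt(abs(exp(-post$lambda / 2) - sigma), 0.05)
  expect_lt(max(abs(post$mean - theta)), 0.1)
})

test_that("posterior stays at the prior mean for zero-noise data from the prior mean", {
  spec <- dcm_model_spec(regions = dcm_regions(2),
                         b_masks = list(difficulty = diag(2) == 1,
                                        interaction = diag(2) == 1))
  prior <- dcm_priors(spec)
  d <- generate_design(seed = 9, n_runs = 1, trials_per_run = 8)
  inp <- dcm_inputs(d$events, d$acquisition, run_dur = d$run_dur, dt = 0.1)
  y0 <- integrate_and_sample(theta_to_params(prior$mean, spec), inp)
  post <- dcm_fit(y0, inp, spec = spec, priors = prior, max_iter = 8)
  expect_lt(sqrt(sum((post$mean - prior$mean) ^ 2)), 1e-3)
})

test_that("free energy is non-decreasing across accepted iterations", {
  spec <- dcm_model_spec(regions = dcm_regions(2),
                         b_masks = list(difficulty = diag(2) == 1,
                                        interaction = diag(2) == 1))
  d <- generate_design(seed = 10, n_runs = 1, trials_per_run = 12)
  p <- sample_population(1, seed = 10, regions = dcm_regions(2))
  ds <- generate_group_dataset(d, p, snr = 2, seed = 10, dt = 0.05)
  inp <- dcm_inputs(d$events, d$acquisition, run_dur = d$run_dur, dt = 0.1)
  post <- dcm_fit(ds$subjects[[1]]$ts, inp, spec = spec, max_iter = 12)
  expect_true(all(diff(post$trace) >= -1e-9))
})

test_that("known intrinsic modulations are recovered from synthetic four-region data", {
  # posterior means of the modulation parameters, pooled over seeds,
  # track the subject-specific ground truth
  spec <- dcm_model_spec(regions = dcm_regions(4),
                         b_masks = list(difficulty = diag(4) == 1,
                                        interaction = diag(4) == 1))
  d <- generate_design(seed = 21, n_runs = 4)
  inp <- dcm_inputs(d$events, d$acquisition, run_dur = d$run_dur, dt = 0.1)
  est <- c(); tru <- c()
  for (s in 1:5) {
    p <- sample_population(1, seed = 40 + s, regions = dcm_regions(4))
    ds <- generate_group_dataset(d, p, snr = 4, seed = 50 + s, dt = 0.05)
    post <- dcm_fit(ds$subjects[[1]]$ts, inp, spec = spec, max_iter = 24,
                    fd = "forward")
    bn <- grep("^B\\.", names(post$mean), value = TRUE)
    est <- c(est, post$mean[bn])
    tru <- c(tru, diag(p[[1]]$dcm$B$difficulty),
             diag(p[[1]]$dcm$B$interaction))
  }
  expect_gt(cor(est, tru), 0.65)
  expect_lt(mean(abs(est - tru)), 0.25)
})

test_that("free_energy decomposition: zero complexity at the prior, noise sensitivity", {
  set.seed(5)
  y <- rnorm(20)
  pred <- rep(0, 20)
  prior <- gaussian_belief(rep(0, 3), diag(2, 3))
  noise1 <- noise_model(groups = rep(1, 20), fixed_precision = 1)
  f1 <- free_energy(y, pred, prior, prior, noise1)
  expect_equal(f1$complexity, 0)
  # inflating the noise variance 10x lowers the accuracy for fixed residuals
  noise10 <- noise_model(groups = rep(1, 20), fixed_precision = 1 / 10)
  f10 <- free_energy(y, pred, prior, prior, noise10)
  expect_lt(f10$accuracy, f1$accuracy)
  expect_error(free_energy(y[1:5], pred, prior, prior, noise1),
               "mismatched")
})
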