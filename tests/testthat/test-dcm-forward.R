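# small helper: inputs with grid-aligned events so the same boxcars are
# representable at every integration step used in a test
aligned_inputs <- function(n_trials = 6, dt = 0.05, run_dur = NULL) {
  onsets <- (seq_len(n_trials) - 1) * 8 + 1.2
  conds <- rep(design_conditions(), length.out = n_trials)
  events <- data.frame(run = 1, onset = onsets, duration = 3.2,
                       condition = conds)
  acq <- data.frame(run = 1, time = (seq_len(n_trials) - 1) * 8 + 4.8)
  dcm_inputs(events, acq, run_dur = run_dur %||% (8 * n_trials), dt = dt)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("neural derivative implements the bilinear form with log self-scaling", {
  p <- dcm_params(regions = dcm_regions(4))
  z <- c(1, -2, 0.5, 0)
  u <- rep(0, 4)
  expect_equal(neural_derivative(z, u, p), -0.5 * z)

  # self-modulation by difficulty: -0.5 exp(b u) with b = -0.47, u = 1
  p2 <- p
  p2$B$difficulty[1, 1] <- -0.47
  u2 <- c(0, 0, 1, 0)
  dz <- neural_derivative(c(1, 0, 0, 0), u2, p2)
  expect_equal(dz[1], -0.5 * exp(-0.47), tolerance = 1e-12)
  expect_gt(dz[1], -0.5)            # disinhibition: slower decay

  # a single driving entry in C only reaches its region
  p3 <- p
  p3$C[2, "trials"] <- 0.7
  dz3 <- neural_derivative(rep(0, 4), c(1, 0, 0, 0), p3)
  expect_equal(dz3, c(0, 0.7, 0, 0))
})

test_that("balloon model rests at its fixed point and reacts to drive", {
  h0 <- c(0, 1, 1, 1)
  expect_equal(hemo_derivative(h0, 0), rep(0, 4))
  d <- hemo_derivative(h0, 0.3)
  expect_gt(d[1], 0)                # signal rises with neural drive
  expect_equal(d[2], 0)             # flow follows the signal, not directly
  expect_error(hemo_derivative(c(0, -1, 1, 1), 0), "positive")
  expect_equal(bold_observation(h0), 0)
  # deoxyhemoglobin washout raises the signal
  expect_gt(bold_observation(c(0, 1, 1, 0.9)), 0)
})

test_that("impulse response peaks 3-7 s after stimulation and returns to rest", {
  p <- dcm_params(regions = dcm_regions(1))
  p$C[1, "trials"] <- 1
  events <- data.frame(run = 1, onset = 0.5, duration = 0.5,
                       condition = "SFG-60")
  acq <- data.frame(run = 1, time = seq(0, 30, by = 0.5))
  inp <- dcm_inputs(events, acq, run_dur = 30.5, dt = 0.05)
  ts <- integrate_and_sample(p, inp)
  y <- ts$data[, 1]
  tpk <- acq$time[which.max(y)] - 0.5
  expect_gte(tpk, 3)
  expect_lte(tpk, 7)
  # dissipativity: signal decays back toward rest after offset
  expect_lt(abs(y[length(y)]), 0.05 * max(y))
})

test_that("zero drive gives flat output; run structure is preserved", {
  d <- generate_design(seed = 4, n_runs = 2)
  inp <- dcm_inputs(d$events, d$acquisition, run_dur = d$run_dur)
  p <- dcm_params(regions = dcm_regions(4))        # C = 0
  ts <- integrate_and_sample(p, inp)
  expect_equal(max(abs(ts$data)), 0)
  expect_equal(nrow(ts$data), 48)
  expect_equal(as.integer(table(ts$run)), c(24L, 24L))
  # acquisition spacing 8 s within runs
  expect_true(all(abs(diff(d$acquisition$time[d$acquisition$run == 1]) - 8)
                  < 1e-12))
})

test_that("step-doubling: halving the step changes sampled BOLD by < 1e-4 relative", {
  p <- sample_population(1, seed = 2, regions = dcm_regions(4))[[1]]$dcm
  y1 <- integrate_and_sample(p, aligned_inputs(dt = 0.05))$data
  y2 <- integrate_and_sample(p, aligned_inputs(dt = 0.025))$data
  expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-4)
})

test_that("compiled and reference integrators agree", {
  p <- sample_population(1, seed = 3, regions = dcm_regions(2))[[1]]$dcm
  inp <- aligned_inputs(n_trials = 3, dt = 0.1)
  y_cpp <- integrate_and_sample(p, inp, engine = "cpp")$data
  y_r <- integrate_and_sample(p, inp, engine = "r")$data
  expect_lt(max(abs(y_cpp - y_r)), 1e-10)
})

test_that("sampled BOLD is near-linear in small drive amplitudes", {
  p <- dcm_params(regions = dcm_regions(2))
  p$C[, "trials"] <- c(0.3, 0.2)
  inp <- aligned_inputs(n_trials = 4)
  scale_by <- function(e) {
    ps <- p
    ps$C <- p$C * e
    integrate_and_sample(ps, inp)$data
  }
  y1 <- scale_by(1e-3)
  y2 <- scale_by(2e-3)
  expect_lt(max(abs(y2 - 2 * y1)) / max(abs(y2)), 1e-3)
})

test_that("self-connections stay negative over the design and rest is stable", {
  prof <- sample_population(1, seed = 5, regions = dcm_regions(4))[[1]]
  p <- prof$dcm
  for (u in list(rep(0, 4), c(1, 0.5, 0.5, 0.25), c(1, -0.5, -0.5, 0.25))) {
    M <- p$A
    for (j in seq_along(u)) {
      bn <- names(p$B)
      full <- sfgdcm::dcm_input_names()[j]
      if (full %in% bn) M <- M + u[j] * p$B[[full]]
    }
    Meff <- M
    diag(Meff) <- -0.5 * exp(diag(M))
    expect_true(all(diag(Meff) < 0))
    expect_true(all(Re(eigen(Meff)$values) < 0))   # decays to rest
  }
  # divergence guard names the problem
  bad <- dcm_params(regions = dcm_regions(2))
  bad$A[1, 2] <- bad$A[2, 1] <- 5      # strong positive feedback loop
  bad$C[, "trials"] <- 1
  expect_error(integrate_and_sample(bad, aligned_inputs(n_trials = 2)),
               "unstable")
})
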