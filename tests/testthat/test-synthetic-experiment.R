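test_that("design: balanced conditions, 8-s volume spacing, jittered onsets", {
  d <- generate_design(seed = 6)
  expect_equal(nrow(d$events), 8 * 24)
  tab <- table(d$events$run, d$events$condition)
  expect_true(all(tab == 6))
  for (r in 1:8) {
    at <- d$acquisition$time[d$acquisition$run == r]
    expect_length(at, 24)
    expect_true(all(abs(diff(at) - 8) < 1e-12))
  }
  # stimulus onsets fall 0.4-2.4 s after the end of the previous scan
  # (trial start), and stimuli precede the trial's own acquisition
  rel <- d$events$onset - (d$events$trial - 1) * 8
  expect_true(all(rel >= 0.4 & rel <= 2.4))
})

test_that("population thresholds: ordering, correlations, interaction truths", {
  pop <- sample_population(3000, seed = 8, regions = dcm_regions(2))
  th <- t(vapply(pop, function(p) p$thresholds, numeric(4)))
  expect_true(all(th[, "SFG-90"] > th[, "SFG-60"]))
  expect_true(all(th[, "SPIN-90"] > th[, "SPIN-60"]))
  # between-task rank correlation near its 0.35 target
  r60 <- cor(th[, "SFG-60"], th[, "SPIN-60"], method = "spearman")
  expect_lt(abs(r60 - 0.35), 0.05)
  rw <- cor(th[, "SFG-60"], th[, "SFG-90"], method = "spearman")
  expect_lt(abs(rw - 0.55), 0.05)
  # uncorrelated spec
  pop0 <- sample_population(3000, seed = 9, regions = dcm_regions(2),
                            correlation_spec = list(between_task = 0,
                                                    within_task = 0.55))
  th0 <- t(vapply(pop0, function(p) p$thresholds, numeric(4)))
  expect_lt(abs(cor(th0[, "SFG-60"], th0[, "SPIN-60"],
                    method = "spearman")), 0.06)
  # observers hit their nominal performance at the drawn thresholds
  p1 <- pop[[1]]
  expect_equal(unname(observer_p(p1$observers$SFG, th[1, "SFG-60"])), 0.6,
               tolerance = 1e-9)
  expect_equal(unname(observer_p(p1$observers$SFG, th[1, "SFG-90"])), 0.9,
               tolerance = 1e-9)
  # ground-truth interaction modulations identically zero
  expect_true(all(vapply(pop[1:50], function(p)
    all(p$dcm$B$interaction == 0), TRUE)))
})

test_that("group dataset: noiseless limit, difficulty effect, determinism", {
  d <- generate_design(seed = 11, n_runs = 2)
  pop <- sample_population(2, seed = 11, regions = dcm_regions(2))
  inp <- dcm_inputs(d$events, d$acquisition, run_dur = d$run_dur)
  ds_inf <- generate_group_dataset(d, pop, snr = Inf, seed = 12)
  clean <- integrate_and_sample(pop[[1]]$dcm, inp)$data
  expect_equal(unname(ds_inf$subjects[[1]]$ts$data), unname(clean))

  ds <- generate_group_dataset(d, pop, snr = 2, seed = 12)
  expect_false(isTRUE(all.equal(unname(ds$subjects[[1]]$ts$data),
                                unname(clean))))
  # realized noise is near the requested SNR
  resid <- ds$subjects[[1]]$ts$data - clean
  expect_lt(max(abs(apply(resid, 2, sd) / (apply(clean, 2, sd) / 2) - 1)),
            0.35)

  # accuracy higher in the easy (90%) than hard (60%) conditions
  pop8 <- sample_population(8, seed = 13, regions = dcm_regions(2))
  ds8 <- generate_group_dataset(d, pop8, snr = 2, seed = 13)
  acc <- do.call(rbind, lapply(ds8$subjects, function(s) {
    b <- s$behavior
    tapply(b$correct, grepl("-90$", b$condition), mean)
  }))
  expect_gt(mean(acc[, "TRUE"]), mean(acc[, "FALSE"]))

  # regenerating with the same seed is bit-identical
  ds2 <- generate_group_dataset(d, pop, snr = 2, seed = 12)
  expect_identical(ds$subjects[[1]]$ts$data, ds2$subjects[[1]]$ts$data)
  expect_identical(ds$subjects[[2]]$behavior, ds2$subjects[[2]]$behavior)
  expect_error(generate_group_dataset(d, pop, snr = 0, seed = 1),
               "SNR")
})

test_that("dataset files round-trip deterministically", {
  d <- generate_design(seed = 14, n_runs = 1)
  pop <- sample_population(2, seed = 14, regions = dcm_regions(2))
  ds <- generate_group_dataset(d, pop, snr = 2, seed = 14)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  write_group_dataset(ds, d1)
  write_group_dataset(ds, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("sub-01/timeseries.csv", "sub-01/events.tsv",
                    "covariates.csv", "truth.json") %in% f1))
  md5 <- function(dir) unname(tools::md5sum(
    file.path(dir, list.files(dir, recursive = TRUE))))
  expect_identical(md5(d1), md5(d2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("per-condition behavioral summaries order d-prime by difficulty", {
  d <- generate_design(seed = 15, n_runs = 8)
  pop <- sample_population(1, seed = 15, regions = dcm_regions(2))
  ds <- generate_group_dataset(d, pop, snr = 2, seed = 15)
  bs <- behavior_summary(ds$subjects[[1]]$behavior)
  expect_equal(nrow(bs), 4)
  expect_equal(sum(bs$n), 192)
  d60 <- mean(bs$d_prime[grepl("-60$", bs$condition)])
  d90 <- mean(bs$d_prime[grepl("-90$", bs$condition)])
  expect_gt(d90, d60)
})
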