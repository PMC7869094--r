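#' Simulate a synthetic group experiment and run the full inference chain
#'
#' One self-contained recovery study: draws a population with the default
#' ground truth (difficulty-induced disinhibition of left core and left
#' posteromedial belt, zero interaction modulations), forward-simulates
#' sparse-sampled BOLD at the requested SNR, inverts each subject's DCM by
#' variational Laplace, and runs the group PEB + greedy Bayesian model
#' reduction + Bayesian model averaging.
#'
#' The generating model is integrated at `dt_gen` and inverted at
#' `dt_fit`, so the inversion never sees the generating discretization.
#'
#' @param seed master seed.
#' @param regions region labels for the simulated network.
#' @param n_subjects,n_runs,snr study dimensions.
#' @param intrinsic_only restrict the modulation (B) masks of the fitted
#'   model to self-connections; `FALSE` fits modulations of every
#'   connection as in the full model.
#' @param dt_gen,dt_fit integration steps (s) for generation and fitting.
#' @param max_iter Gauss-Newton cap per subject.
#' @param fd finite-difference scheme for the Jacobians.
#' @param pp_threshold retention threshold on the posterior probability.
#' @param quiet suppress progress messages.
#' @return List with `bma` (a [bayesian_model_average()] result), `models`
#'   (the scored `"model_set"`), `peb`, `posteriors`, `dataset`, and
#'   `retained` (names of group parameters with `Pp >=` the threshold).
#' @export
simulate_and_recover <- function(seed = 1L, regions = dcm_regions(4),
                                 n_subjects = 8, n_runs = 8, snr = 2,
                                 intrinsic_only = TRUE, dt_gen = 0.05,
                                 dt_fit = 0.1, max_iter = 24,
                                 fd = "forward", pp_threshold = 0.95,
                                 quiet = TRUE) {
  design <- generate_design(seed = seed, n_runs = n_runs)
  profiles <- sample_population(n_subjects, seed = seed + 1L,
                                regions = regions)
  ds <- generate_group_dataset(design, profiles, snr = snr,
                               seed = seed + 2L, dt = dt_gen)
  n <- length(regions)
  b_masks <- if (intrinsic_only)
    list(difficulty = diag(n) == 1, interaction = diag(n) == 1) else NULL
  spec <- dcm_model_spec(regions = regions, b_masks = b_masks)
  inputs <- dcm_inputs(design$events, design$acquisition,
                       run_dur = design$run_dur, dt = dt_fit)
  posteriors <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    if (!quiet) message("fitting subject ", s, "/", n_subjects)
    posteriors[[s]] <- suppressWarnings(
      dcm_fit(ds$subjects[[s]]$ts, inputs, spec = spec,
              confounds = ds$subjects[[s]]$motion, max_iter = max_iter,
              fd = fd))
  }
  X <- cbind(mean = 1, ds$covariates)
  peb <- peb_fit(posteriors, X)
  models <- greedy_search(peb)
  bma <- bayesian_model_average(models, threshold = pp_threshold)
  list(bma = bma, models = models, peb = peb, posteriors = posteriors,
       dataset = ds, retained = bma$retained)
}
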