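#' Condition labels of the in-scanner task design
#'
#' Two tasks (figure-ground `SFG`, speech-in-noise `SPIN`) at two
#' difficulty levels (TMRs titrated to 60% and 90% accuracy).
#' @return Character vector of the four condition labels.
#' @export
design_conditions <- function()
  c("SFG-60", "SFG-90", "SPIN-60", "SPIN-90")

#' Generate a sparse-sampling experimental design
#'
#' Trials of `trial_period` seconds with one volume acquired at the end of
#' each trial (sparse temporal sampling: the scanner is silent for
#' `trial_period - tr` seconds, then acquires for `tr` seconds, so
#' successive volume onsets are `trial_period` apart).  Each run holds an
#' equal number of trials per condition, pseudorandomly interleaved, and
#' stimulus onsets are jittered uniformly 0.4-2.4 s after the end of the
#' previous volume acquisition.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param n_runs number of runs.
#' @param trials_per_run trials per run (must be divisible by 4).
#' @param trial_period trial duration (s); volume spacing.
#' @param tr volume acquisition duration (s).
#' @param stim_dur stimulus duration (s).
#' @param jitter earliest/latest stimulus onset after the previous scan
#'   end (s).
#' @return Object of class `"experiment_design"`: `events` (run, trial,
#'   onset, duration, condition; onsets in within-run seconds),
#'   `acquisition` (run, time of each volume onset), and the timing
#'   parameters.
#' @export
generate_design <- function(seed = 1L, n_runs = 8, trials_per_run = 24,
                            trial_period = 8, tr = 3.36, stim_dur = 3.1,
                            jitter = c(0.4, 2.4)) {
  if (!is.null(seed)) set.seed(seed)
  conds <- design_conditions()
  if (trials_per_run %% length(conds) != 0)
    stop("trials_per_run must be divisible by the number of conditions")
  per_cond <- trials_per_run / length(conds)
  gap <- trial_period - tr                      # silent gap before the scan
  events <- list(); acq <- list()
  for (r in seq_len(n_runs)) {
    order <- sample(rep(conds, per_cond))
    starts <- (seq_len(trials_per_run) - 1) * trial_period
    onsets <- starts + stats::runif(trials_per_run, jitter[1], jitter[2])
    events[[r]] <- data.frame(run = r, trial = seq_len(trials_per_run),
                              onset = onsets, duration = stim_dur,
                              condition = order)
    acq[[r]] <- data.frame(run = r, time = starts + gap)
  }
  structure(list(events = do.call(rbind, events),
                 acquisition = do.call(rbind, acq),
                 n_runs = n_runs, trials_per_run = trials_per_run,
                 trial_period = trial_period, tr = tr, stim_dur = stim_dur,
                 jitter = jitter, run_dur = trials_per_run * trial_period),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "design: %d runs x %d trials (%g s each), TR %g s, %g s volume spacing\n",
    x$n_runs, x$trials_per_run, x$trial_period, x$tr, x$trial_period))
  invisible(x)
}

# group-mean ground-truth connectivity for a given region set: a
# bottom-up/top-down hierarchy (core -> belt -> higher cortex) per
# hemisphere, difficulty-induced disinhibition of left core and left
# posteromedial belt, no interaction modulations, driving input to core.
truth_group_dcm <- function(regions = dcm_regions(),
                            b_intrinsic = c("lTe1.0" = -0.47,
                                            "lTe1.1" = -0.51),
                            drive = 0.4) {
  n <- length(regions)
  A <- matrix(0, n, n, dimnames = list(regions, regions))
  link <- function(to, from, w) {
    if (to %in% regions && from %in% regions) A[to, from] <<- w
  }
  for (h in c("l", "r")) {
    link(paste0(h, "Te1.1"), paste0(h, "Te1.0"), 0.20)
    link(paste0(h, "Te1.2"), paste0(h, "Te1.0"), 0.20)
    link(paste0(h, "Te3"), paste0(h, "Te1.1"), 0.20)
    link(paste0(h, "Te3"), paste0(h, "Te1.2"), 0.20)
    link(paste0(h, "Te1.0"), paste0(h, "Te1.1"), 0.10)
    link(paste0(h, "Te1.0"), paste0(h, "Te1.2"), 0.10)
    link(paste0(h, "Te1.1"), paste0(h, "Te3"), 0.10)
    link(paste0(h, "Te1.2"), paste0(h, "Te3"), 0.10)
  }
  B <- list(difficulty = matrix(0, n, n, dimnames = list(regions, regions)),
            interaction = matrix(0, n, n, dimnames = list(regions, regions)))
  for (rg in names(b_intrinsic))
    if (rg %in% regions) B$difficulty[rg, rg] <- b_intrinsic[[rg]]
  C <- matrix(0, n, 4, dimnames = list(regions, dcm_input_names()))
  for (rg in c("lTe1.0", "rTe1.0"))
    if (rg %in% regions) C[rg, "trials"] <- drive
  dcm_params(A = A, B = B, C = C, regions = regions)
}

#' Draw a population of subject profiles
#'
#' Thresholds (TMR, dB) for the four conditions are drawn from a Gaussian
#' copula with configurable between-task and within-task rank
#' correlations; each subject's psychometric observers are constructed so
#' that they perform at exactly 60% and 90% at their respective
#' thresholds.  Ground-truth connectivity per subject is the group mean
#' (difficulty-induced disinhibition of left core/posteromedial belt, no
#' interaction modulations) plus Gaussian between-subject variation on
#' the nonzero entries.
#'
#' @param n_subjects number of subjects.
#' @param correlation_spec list with `between_task` and `within_task` rank
#'   correlations of thresholds.
#' @param seed integer seed, or `NULL`.
#' @param regions region labels for the ground-truth DCM.
#' @param threshold_mean named means (dB) of the condition thresholds.
#' @param threshold_sd between-subject SD (dB) of each threshold.
#' @param between_sd between-subject SD of nonzero connectivity
#'   parameters.
#' @param lapse observer lapse rate.
#' @return List of `"subject_profile"` objects: `thresholds` (named
#'   vector over conditions), `observers` (per task), `dcm` (a
#'   [dcm_params()] ground truth).
#' @export
sample_population <- function(n_subjects = 8,
                              correlation_spec = list(between_task = 0.35,
                                                      within_task = 0.55),
                              seed = 1L, regions = dcm_regions(),
                              threshold_mean = c("SFG-60" = -4, "SFG-90" = 0,
                                                 "SPIN-60" = -8,
                                                 "SPIN-90" = -4),
                              threshold_sd = 2, between_sd = 0.1,
                              lapse = 0.02) {
  if (!is.null(seed)) set.seed(seed)
  conds <- design_conditions()
  # rank correlation of a bivariate Gaussian -> Pearson correlation
  r2p <- function(rs) 2 * sin(pi * rs / 6)
  bt <- r2p(correlation_spec$between_task %||% 0.35)
  wt <- r2p(correlation_spec$within_task %||% 0.55)
  R <- matrix(bt, 4, 4, dimnames = list(conds, conds))
  R["SFG-60", "SFG-90"] <- R["SFG-90", "SFG-60"] <- wt
  R["SPIN-60", "SPIN-90"] <- R["SPIN-90", "SPIN-60"] <- wt
  diag(R) <- 1
  L <- chol(R)
  truth <- truth_group_dcm(regions)
  nz_a <- which(truth$A != 0 & row(truth$A) != col(truth$A))
  nz_b <- lapply(truth$B, function(bm) which(bm != 0))
  draw_thresholds <- function() {
    repeat {
      th <- threshold_mean + threshold_sd * drop(crossprod(L, stats::rnorm(4)))
      names(th) <- conds
      # the easy (90%) condition needs a more favorable TMR than the hard
      # (60%) one; resample rare violations (and near-degenerate slopes)
      if (th["SFG-90"] - th["SFG-60"] > 0.5 &&
          th["SPIN-90"] - th["SPIN-60"] > 0.5)
        return(th)
    }
  }
  make_observer <- function(t60, t90) {
    l60 <- stats::qlogis(0.6 / (1 - lapse))
    l90 <- stats::qlogis(0.9 / (1 - lapse))
    slope <- (l90 - l60) / (t90 - t60)
    observer(threshold_db = t60 - l60 / slope, slope = slope,
             guess = 0, lapse = lapse)
  }
  lapply(seq_len(n_subjects), function(s) {
    th <- draw_thresholds()
    dcm <- truth
    dcm$A[nz_a] <- dcm$A[nz_a] + between_sd * stats::rnorm(length(nz_a))
    for (b in names(dcm$B)) {
      idx <- nz_b[[b]]
      if (length(idx))
        dcm$B[[b]][idx] <- dcm$B[[b]][idx] +
          between_sd * stats::rnorm(length(idx))
    }
    structure(list(thresholds = th,
                   observers = list(SFG = make_observer(th["SFG-60"],
                                                        th["SFG-90"]),
                                    SPIN = make_observer(th["SPIN-60"],
                                                         th["SPIN-90"])),
                   dcm = dcm), class = "subject_profile")
  })
}

# smooth low-amplitude nuisance series (simulated head motion parameters)
simulate_motion <- function(nscan, k = 6, amplitude = 0.1) {
  m <- vapply(seq_len(k), function(i) {
    x <- stats::filter(stats::rnorm(nscan + 20), rep(1 / 10, 10),
                       sides = 1)
    amplitude * scale(x[21:(nscan + 20)])[, 1]
  }, numeric(nscan))
  colnames(m) <- paste0("motion", seq_len(k))
  m
}

#' Generate a complete multi-subject synthetic dataset
#'
#' For each subject: builds the DCM inputs from the event table,
#' integrates that subject's ground-truth forward model, adds white
#' Gaussian observation noise at the stated SNR (per-region noise SD =
#' SD of the noiseless signal / SNR), simulates yes/no behavior from the
#' subject's observers at the fixed per-condition TMRs, and packages the
#' per-condition TMR covariates used by the group model.
#'
#' @param design an [generate_design()] object.
#' @param profiles list of subject profiles from [sample_population()].
#' @param snr signal-to-noise ratio (SD of signal over SD of noise);
#'   `Inf` for noiseless data.
#' @param seed integer master seed; per-subject substreams are derived
#'   from it.
#' @param dt integration step (s).
#' @return Object of class `"group_dataset"`: per-subject `ts`
#'   (`"roi_timeseries"`), `behavior` (trial table), `motion`, plus the
#'   shared `design`, `inputs`, `covariates` (subjects x conditions TMR
#'   matrix), ground-truth records, `snr`, and `seed`.
#' @export
generate_group_dataset <- function(design, profiles, snr = 2, seed = 1L,
                                   dt = 0.05) {
  if (snr <= 0) stop("SNR must be positive")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(profiles))
  regions <- profiles[[1]]$dcm$regions
  inputs <- dcm_inputs(design$events, design$acquisition,
                       run_dur = design$run_dur, dt = dt)
  conds <- design_conditions()
  subjects <- vector("list", length(profiles))
  for (s in seq_along(profiles)) {
    set.seed(sub_seeds[s])
    prof <- profiles[[s]]
    ts <- integrate_and_sample(prof$dcm, inputs)
    sig_sd <- apply(ts$data, 2, stats::sd)
    noise_sd <- if (is.finite(snr)) sig_sd / snr else rep(0, ncol(ts$data))
    if (any(sig_sd == 0) && any(sig_sd > 0))
      noise_sd[sig_sd == 0] <- mean(noise_sd[sig_sd > 0])
    if (any(noise_sd > 0))
      ts$data <- ts$data + matrix(stats::rnorm(length(ts$data)),
                                  nrow(ts$data)) %*% diag(noise_sd,
                                                          ncol(ts$data))
    colnames(ts$data) <- regions
    ev <- design$events
    task <- ifelse(grepl("^SPIN", ev$condition), "SPIN", "SFG")
    tmr <- prof$thresholds[as.character(ev$condition)]
    p <- mapply(function(tk, tm) observer_p(prof$observers[[tk]], tm),
                task, tmr)
    present <- stats::runif(nrow(ev)) < 0.5
    correct <- stats::runif(nrow(ev)) < p
    response <- ifelse(correct, present, !present)
    behavior <- data.frame(run = ev$run, trial = ev$trial,
                           condition = ev$condition, tmr_db = unname(tmr),
                           target_present = present, response_yes = response,
                           correct = correct)
    subjects[[s]] <- list(ts = ts, behavior = behavior,
                          motion = simulate_motion(nrow(ts$data)),
                          thresholds = prof$thresholds,
                          truth = prof$dcm)
  }
  covariates <- t(vapply(profiles, function(p) p$thresholds[conds],
                         numeric(4)))
  colnames(covariates) <- conds
  structure(list(subjects = subjects, design = design, inputs = inputs,
                 covariates = covariates, regions = regions,
                 snr = snr, seed = seed,
                 truth_group = truth_group_dcm(regions)),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf(
    "group dataset: %d subjects, %d regions, %d runs, SNR %.3g, seed %d\n",
    length(x$subjects), length(x$regions), x$design$n_runs, x$snr, x$seed))
  invisible(x)
}

#' Signal-detection summary of simulated behavior, per condition
#'
#' @param behavior a per-trial behavior table (as in a
#'   [generate_group_dataset()] subject).
#' @return Data frame with one row per condition: counts, d-prime and
#'   criterion (loglinear-corrected), and proportion correct.
#' @export
behavior_summary <- function(behavior) {
  out <- lapply(split(behavior, behavior$condition), function(b) {
    hits <- sum(b$target_present & b$response_yes)
    misses <- sum(b$target_present & !b$response_yes)
    fas <- sum(!b$target_present & b$response_yes)
    crs <- sum(!b$target_present & !b$response_yes)
    dp <- dprime_loglinear(hits, misses, fas, crs)
    data.frame(condition = b$condition[1], n = nrow(b), hits = hits,
               misses = misses, fas = fas, crs = crs,
               d_prime = dp$d_prime, criterion_c = dp$criterion_c,
               prop_correct = mean(b$correct))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a group dataset to a directory of plain-text files
#'
#' Layout: `sub-XX/timeseries.csv`, `sub-XX/events.tsv` (columns onset,
#' duration, trial_type, run), `sub-XX/behavior.csv`, `sub-XX/motion.csv`,
#' `covariates.csv`, `truth.json`, `config.json`.
#'
#' @param ds a [generate_group_dataset()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_group_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(ds$subjects)) {
    sd_ <- file.path(dir, sprintf("sub-%02d", s))
    dir.create(sd_, showWarnings = FALSE)
    sub <- ds$subjects[[s]]
    tsdf <- data.frame(scan = seq_len(nrow(sub$ts$data)), run = sub$ts$run,
                       sub$ts$data, check.names = FALSE)
    utils::write.csv(tsdf, file.path(sd_, "timeseries.csv"),
                     row.names = FALSE)
    ev <- ds$design$events
    utils::write.table(
      data.frame(onset = ev$onset, duration = ev$duration,
                 trial_type = ev$condition, run = ev$run),
      file.path(sd_, "events.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    utils::write.csv(sub$behavior, file.path(sd_, "behavior.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sub$motion),
                     file.path(sd_, "motion.csv"), row.names = FALSE)
  }
  cov <- data.frame(subject = seq_len(nrow(ds$covariates)),
                    ds$covariates, check.names = FALSE)
  utils::write.csv(cov, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- list(
    regions = ds$regions,
    group = list(A = unname(ds$truth_group$A),
                 B = lapply(ds$truth_group$B, unname),
                 C = unname(ds$truth_group$C)),
    subjects = lapply(ds$subjects, function(s)
      list(A = unname(s$truth$A), B = lapply(s$truth$B, unname),
           C = unname(s$truth$C), thresholds = as.list(s$thresholds))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = ds$seed, snr = ds$snr,
                            n_subjects = length(ds$subjects),
                            n_runs = ds$design$n_runs,
                            trials_per_run = ds$design$trials_per_run,
                            regions = ds$regions),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
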