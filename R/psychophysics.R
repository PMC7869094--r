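#' Simulated listener with a logistic psychometric function
#'
#' Stand-in for a human observer in threshold simulations.  The probability
#' of a correct response at a given target-to-masker ratio (TMR) is
#' `guess + (1 - guess - lapse) * plogis(slope * (tmr - threshold_db))`,
#' which is monotone nondecreasing in TMR.
#'
#' @param threshold_db TMR (dB) at the inflection of the psychometric
#'   function.
#' @param slope psychometric slope in 1/dB.
#' @param guess lower asymptote (guessing rate).
#' @param lapse lapse rate (1 - upper asymptote).
#' @return An object of class `"observer"`.
#' @export
observer <- function(threshold_db = 0, slope = 1, guess = 0, lapse = 0.02) {
  if (guess < 0 || guess >= 0.5 || lapse < 0 || lapse >= 0.5)
    stop("guess and lapse must lie in [0, 0.5)")
  if (slope <= 0) stop("slope must be positive")
  structure(list(threshold_db = threshold_db, slope = slope,
                 guess = guess, lapse = lapse), class = "observer")
}

#' Probability of a correct response at a given TMR
#'
#' @param obs an [observer()].
#' @param tmr_db TMR in dB (vectorized).
#' @return Probability of a correct response.
#' @export
observer_p <- function(obs, tmr_db) {
  obs$guess + (1 - obs$guess - obs$lapse) *
    stats::plogis(obs$slope * (tmr_db - obs$threshold_db))
}

#' TMR at which an observer reaches a target percent correct
#'
#' Inverts the psychometric function of [observer()].
#'
#' @param obs an [observer()].
#' @param p target probability correct (must lie strictly between `guess`
#'   and `1 - lapse`).
#' @return TMR in dB.
#' @export
observer_quantile <- function(obs, p) {
  if (any(p <= obs$guess) || any(p >= 1 - obs$lapse))
    stop("target proportion outside the observer's achievable range")
  q <- (p - obs$guess) / (1 - obs$guess - obs$lapse)
  obs$threshold_db + stats::qlogis(q) / obs$slope
}

#' Initialize a weighted up-down adaptive track
#'
#' One run of the weighted (asymmetric-step) up-down procedure: the TMR
#' increases by the base step after an incorrect response and decreases by
#' `base_step / step_ratio` after a correct response, so the track
#' converges where p(correct) = step_ratio / (step_ratio + 1) (0.90 for
#' the 9:1 preset, used for 90% thresholds).  The base (up) step starts at
#' 1 dB and halves to 0.5 dB after the 3rd reversal; the track terminates
#' after 10 reversals.  Taking the up-step as the base keeps the sawtooth
#' excursions small, so the median of the final reversals sits at the
#' convergence point rather than half an up-jump above it.
#'
#' @param start_tmr starting TMR in dB.
#' @param step_ratio up-step : down-step ratio (9 for the 90% preset, 6 for
#'   the 60% preset).
#' @param base_step initial base (up) step in dB.
#' @param small_step base step after `switch_after` reversals.
#' @param switch_after number of reversals after which the base step
#'   switches to `small_step`.
#' @param max_reversals number of reversals at which the track terminates.
#' @return An object of class `"staircase"`.
#' @export
staircase <- function(start_tmr = 0, step_ratio = 9, base_step = 1,
                      small_step = 0.5, switch_after = 3,
                      max_reversals = 10) {
  structure(list(tmr = start_tmr, step_ratio = step_ratio,
                 base_step = base_step, initial_step = base_step,
                 small_step = small_step, switch_after = switch_after,
                 max_reversals = max_reversals,
                 n_reversals = 0L, reversal_values = numeric(0),
                 last_direction = 0,      # -1 down, +1 up, 0 none yet
                 history = list(tmr = numeric(0), correct = logical(0),
                                reversal = logical(0)),
                 terminated = FALSE), class = "staircase")
}

#' Advance a weighted up-down track by one trial
#'
#' @param track a [staircase()].
#' @param correct logical; was the response on this trial correct?
#' @return The updated track.  A reversal is recorded (at the pre-update
#'   TMR) whenever the direction of change flips; the base step halves
#'   after the 3rd reversal and the track terminates after the 10th.  The
#'   trial log lives in `track$history` (parallel vectors `tmr`,
#'   `correct`, `reversal`); [staircase_log()] returns it as a data frame.
#' @export
staircase_update <- function(track, correct) {
  if (track$terminated) stop("track already terminated (10 reversals)")
  direction <- if (correct) -1 else 1
  reversal <- track$last_direction != 0 && direction != track$last_direction
  if (reversal) {
    track$n_reversals <- track$n_reversals + 1L
    track$reversal_values <- c(track$reversal_values, track$tmr)
    if (track$n_reversals == track$switch_after)
      track$base_step <- track$small_step
    if (track$n_reversals >= track$max_reversals) track$terminated <- TRUE
  }
  track$history$tmr <- c(track$history$tmr, track$tmr)
  track$history$correct <- c(track$history$correct, correct)
  track$history$reversal <- c(track$history$reversal, reversal)
  step <- if (correct) -track$base_step / track$step_ratio else
    track$base_step
  if (!track$terminated) track$tmr <- track$tmr + step
  track$last_direction <- direction
  track
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf(
    "weighted up-down track: ratio %g:1, tmr %.2f dB, %d reversals%s\n",
    x$step_ratio, x$tmr, x$n_reversals,
    if (x$terminated) " (terminated)" else ""))
  invisible(x)
}

#' Run one adaptive track against a simulated observer
#'
#' @param obs an [observer()].
#' @param track a [staircase()]; defaults to the 9:1 preset starting at
#'   0 dB.
#' @param max_trials safety cap on the number of trials.
#' @return The terminated track.
#' @export
simulate_staircase <- function(obs, track = staircase(), max_trials = 1000) {
  for (i in seq_len(max_trials)) {
    if (track$terminated) break
    correct <- stats::runif(1) < observer_p(obs, track$tmr)
    track <- staircase_update(track, correct)
  }
  track
}

#' Trial log of a track as a data frame
#'
#' @param track a [staircase()].
#' @return Data frame with `trial`, `tmr`, `correct`, `reversal`.
#' @export
staircase_log <- function(track) {
  data.frame(trial = seq_along(track$history$tmr),
             tmr = track$history$tmr, correct = track$history$correct,
             reversal = track$history$reversal)
}

#' Threshold estimate from a completed track
#'
#' The threshold of one run is the median of its last six reversal TMRs.
#'
#' @param track a terminated [staircase()] (at least 10 reversals).
#' @param n_last number of final reversals used.
#' @return Threshold in dB.
#' @export
estimate_threshold <- function(track, n_last = 6) {
  if (track$n_reversals < track$max_reversals)
    stop("incomplete track: fewer than ", track$max_reversals, " reversals")
  vals <- utils::tail(track$reversal_values, n_last)
  stats::median(vals)
}

#' Block threshold from two interleaved runs
#'
#' @param track1,track2 terminated tracks of one block.
#' @return Mean of the two run thresholds, in dB.
#' @export
block_threshold <- function(track1, track2) {
  mean(c(estimate_threshold(track1), estimate_threshold(track2)))
}

#' Simulate a batch of adaptive tracks and recover thresholds
#'
#' @param obs an [observer()].
#' @param n_tracks number of independent tracks.
#' @param step_ratio up:down step ratio.
#' @param start_tmr starting TMR in dB.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return Data frame with one row per track: `track`, `threshold_db`,
#'   `n_trials`.
#' @export
simulate_staircase_batch <- function(obs, n_tracks = 1000, step_ratio = 9,
                                     start_tmr = 0, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  res <- vapply(seq_len(n_tracks), function(i) {
    tr <- simulate_staircase(obs, staircase(start_tmr = start_tmr,
                                            step_ratio = step_ratio))
    c(estimate_threshold(tr), length(tr$history$tmr))
  }, numeric(2))
  data.frame(track = seq_len(n_tracks), threshold_db = res[1, ],
             n_trials = res[2, ])
}

#' Sensitivity and bias from yes/no counts with loglinear correction
#'
#' Computes d-prime and the criterion c from hit/miss/false-alarm/correct-
#' rejection counts.  The loglinear correction adds 0.5 to each cell and 1
#' to each total before forming rates, so the result is finite even for
#' perfect performance.  Trials without a response should be folded into
#' the miss and false-alarm counts by the caller.
#'
#' @param hits,misses,fas,crs nonnegative trial counts.
#' @return A list of class `"behavioral_summary"` with `d_prime`,
#'   `criterion_c`, `hit_rate`, `fa_rate`.
#' @export
dprime_loglinear <- function(hits, misses, fas, crs) {
  counts <- c(hits, misses, fas, crs)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (all(counts == 0)) stop("d-prime undefined for all-zero counts")
  h <- (hits + 0.5) / (hits + misses + 1)
  f <- (fas + 0.5) / (fas + crs + 1)
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  structure(list(d_prime = zh - zf, criterion_c = -(zh + zf) / 2,
                 hit_rate = h, fa_rate = f), class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf("d' = %.3f, c = %.3f (H = %.3f, F = %.3f)\n",
              x$d_prime, x$criterion_c, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Rank correlation of two paired vectors; the confidence interval applies
#' the Fisher z-transform to the rank correlation with standard error
#' `1 / sqrt(n - 3)`.
#'
#' @param x,y paired numeric vectors (no missing values, n >= 4).
#' @param conf confidence level.
#' @return A list with `r_s`, `ci` (length-2 vector), `n`, and the
#'   permutation-free asymptotic `p_value` (t approximation).
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r_s <- stats::cor(x, y, method = "spearman")
  z <- atanh(min(max(r_s, -1 + 1e-12), 1 - 1e-12))
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  ci <- tanh(c(z - hw, z + hw))
  tstat <- r_s * sqrt((n - 2) / (1 - r_s ^ 2 + 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r_s = r_s, ci = ci, n = n, p_value = p)
}
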