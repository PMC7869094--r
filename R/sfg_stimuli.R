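#' Stimulus parameters for stochastic figure-ground (SFG) tone clouds
#'
#' Returns the parameter set describing one figure-ground stimulus: a cloud
#' of 50-ms chords whose background tones are redrawn every chord, with an
#' embedded "figure" of fixed-frequency components that repeat across chords.
#' Defaults reproduce the stimulus family used for auditory figure-ground
#' testing: 62 background chords (3100 ms), a 42-chord (2100 ms) figure of 3
#' components starting 10 chords (500 ms) after background onset, and a
#' 4-chord (200 ms) gap placed either in the figure or in the background.
#'
#' @param chord_dur chord duration in seconds.
#' @param ramp_dur raised-cosine on/off ramp duration in seconds.
#' @param freq_lo,freq_hi frequency grid bounds in Hz.
#' @param grid_step grid spacing in octaves (1/24 octave by default).
#' @param n_bg_min,n_bg_max minimum/maximum number of background tones per
#'   chord.
#' @param n_fig number of figure components.
#' @param n_fig_chords number of chords the figure spans.
#' @param n_bg_chords total number of chords (background duration).
#' @param fig_onset_chords chords between background onset and figure onset.
#' @param gap_chords length of the gap in chords.
#' @param gap_onset_min,gap_onset_max admissible gap onsets, in chords after
#'   stimulus onset.
#' @param sample_rate audio sample rate in Hz.
#' @return An object of class `"sfg_params"` (a named list).
#' @export
sfg_params <- function(chord_dur = 0.050, ramp_dur = 0.010,
                       freq_lo = 179, freq_hi = 7246, grid_step = 1 / 24,
                       n_bg_min = 5, n_bg_max = 15,
                       n_fig = 3, n_fig_chords = 42, n_bg_chords = 62,
                       fig_onset_chords = 10, gap_chords = 4,
                       gap_onset_min = 20, gap_onset_max = 42,
                       sample_rate = 44100) {
  p <- list(chord_dur = chord_dur, ramp_dur = ramp_dur,
            freq_lo = freq_lo, freq_hi = freq_hi, grid_step = grid_step,
            n_bg_min = n_bg_min, n_bg_max = n_bg_max,
            n_fig = n_fig, n_fig_chords = n_fig_chords,
            n_bg_chords = n_bg_chords, fig_onset_chords = fig_onset_chords,
            gap_chords = gap_chords, gap_onset_min = gap_onset_min,
            gap_onset_max = gap_onset_max, sample_rate = sample_rate)
  counts <- c(n_bg_min, n_bg_max, n_fig_chords, n_bg_chords, gap_chords)
  if (any(counts <= 0) || n_fig < 0)
    stop("all stimulus counts must be positive (n_fig may be zero)")
  if (fig_onset_chords + n_fig_chords > n_bg_chords)
    stop("figure must end within the background (fig_onset_chords + n_fig_chords <= n_bg_chords)")
  if (freq_lo >= freq_hi) stop("freq_lo must be below freq_hi")
  if (grid_step <= 0) stop("grid_step must be positive")
  class(p) <- "sfg_params"
  p
}

#' Logarithmic frequency grid for SFG stimuli
#'
#' All tone frequencies (figure and background) are drawn from a logarithmic
#' grid between `freq_lo` and `freq_hi` with `grid_step`-octave spacing, so
#' consecutive grid frequencies differ by a factor `2^grid_step`.
#'
#' @param params an [sfg_params()] object.
#' @return Numeric vector of frequencies in Hz, starting at `freq_lo`; the
#'   last element does not exceed `freq_hi`.
#' @export
build_frequency_grid <- function(params = sfg_params()) {
  if (params$freq_lo >= params$freq_hi) stop("invalid frequency bounds")
  if (params$grid_step <= 0) stop("grid_step must be positive")
  n <- floor(log2(params$freq_hi / params$freq_lo) / params$grid_step) + 1
  params$freq_lo * 2 ^ (params$grid_step * (seq_len(n) - 1))
}

#' Sample the chord structure of one SFG stimulus
#'
#' Draws one figure-ground trial: every chord receives 5-15 background tones
#' at frequencies drawn independently from the grid, and chords inside the
#' figure interval additionally receive the figure components, whose
#' frequencies are drawn once per trial (without replacement) and stay fixed
#' for the whole figure.  One 4-chord gap is placed inside the figure
#' interval: for `gap_in_figure = TRUE` the figure components are omitted
#' during the gap; otherwise 3 background tones are removed from each gap
#' chord instead, so both conditions lose the same number of tone slots.
#'
#' Figure tones are added on top of the background tones (they may coincide
#' in frequency with background tones, so figures cannot be found by
#' spectral separation alone).
#'
#' @param params an [sfg_params()] object.
#' @param gap_in_figure logical; if `TRUE` the gap interrupts the figure,
#'   otherwise it removes background tones while the figure continues.
#' @param seed integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream.
#' @return An object of class `"sfg_stimulus"`: a list with `chords` (list
#'   of background-frequency vectors per chord), `figure` (list of figure
#'   frequencies per chord; zero-length outside the figure or during a
#'   figure gap), `figure_freqs`, `gap_in_figure`, `gap_onset` (0-based
#'   chord index), `params`, and (after synthesis) `waveform`/`tmr_db`.
#' @export
sample_stimulus <- function(params = sfg_params(), gap_in_figure = TRUE,
                            seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  grid <- build_frequency_grid(params)
  nch <- params$n_bg_chords
  fig_start <- params$fig_onset_chords              # 0-based, half-open
  fig_end <- fig_start + params$n_fig_chords        # exclusive

  figure_freqs <- if (params$n_fig > 0)
    sort(sample(grid, params$n_fig, replace = FALSE)) else numeric(0)

  # Gap onset: uniform integer on [gap_onset_min, gap_onset_max] chords after
  # stimulus onset, clipped so the whole gap lies inside the figure interval.
  lo <- max(params$gap_onset_min, fig_start)
  hi <- min(params$gap_onset_max, fig_end - params$gap_chords)
  if (hi < lo) stop("gap cannot be placed inside the figure interval")
  gap_onset <- sample(lo:hi, 1L)
  gap_idx <- gap_onset + seq_len(params$gap_chords) - 1L   # 0-based chords

  chords <- vector("list", nch)
  figure <- vector("list", nch)
  for (k in seq_len(nch)) {
    i <- k - 1L                                      # 0-based chord index
    n_bg <- sample(params$n_bg_min:params$n_bg_max, 1L)
    in_gap <- i %in% gap_idx
    if (!gap_in_figure && in_gap) {
      # background gap: remove 3 randomly chosen tones from this chord;
      # resample the tone count if it would leave fewer than 0 tones
      while (n_bg < params$n_fig)
        n_bg <- sample(params$n_bg_min:params$n_bg_max, 1L)
      bg <- sample(grid, n_bg, replace = FALSE)
      drop <- sample(n_bg, params$n_fig)
      chords[[k]] <- bg[-drop]
    } else {
      chords[[k]] <- sample(grid, n_bg, replace = FALSE)
    }
    in_fig <- params$n_fig > 0 && i >= fig_start && i < fig_end
    figure[[k]] <- if (in_fig && !(gap_in_figure && in_gap))
      figure_freqs else numeric(0)
  }

  structure(list(chords = chords, figure = figure,
                 figure_freqs = figure_freqs,
                 gap_in_figure = gap_in_figure, gap_onset = gap_onset,
                 params = params, waveform = NULL, tmr_db = NA_real_),
            class = "sfg_stimulus")
}

#' @export
print.sfg_stimulus <- function(x, ...) {
  p <- x$params
  cat(sprintf("SFG stimulus: %d chords x %.0f ms, figure of %d components,\n",
              p$n_bg_chords, 1000 * p$chord_dur, p$n_fig))
  cat(sprintf("  gap of %d chords at chord %d (%s), %s\n",
              p$gap_chords, x$gap_onset,
              if (x$gap_in_figure) "in figure" else "in background",
              if (is.null(x$waveform)) "not yet synthesized"
              else sprintf("synthesized at TMR %.1f dB", x$tmr_db)))
  invisible(x)
}

# one ramped tone segment of chord_dur seconds at unit amplitude
tone_segment <- function(freq, params) {
  sr <- params$sample_rate
  n <- round(params$chord_dur * sr)
  t <- (seq_len(n) - 1) / sr
  env <- rep(1, n)
  nr <- round(params$ramp_dur * sr)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  env[seq_len(nr)] <- ramp
  env[n + 1 - seq_len(nr)] <- ramp
  sin(2 * pi * freq * t) * env
}

#' Render an SFG stimulus to a waveform at a given target-to-masker ratio
#'
#' Each tone is a `chord_dur` sinusoid with raised-cosine on/off ramps;
#' chords abut with no inter-chord silence.  All tones within a class
#' (figure or background) share one amplitude, and the figure tones are
#' scaled so that `20*log10(RMS(figure) / RMS(background)) = tmr_db`, where
#' the RMS values are taken over the summed figure and summed background
#' renders of the whole stimulus.  The final waveform is peak-normalized to
#' 0.9.
#'
#' @param stim an `"sfg_stimulus"` from [sample_stimulus()].
#' @param tmr_db target-to-masker ratio in dB.
#' @param normalize logical; peak-normalize the mixed waveform.
#' @return The stimulus with `waveform` (numeric vector) and `tmr_db` set.
#' @export
synthesize_waveform <- function(stim, tmr_db = 0, normalize = TRUE) {
  params <- stim$params
  if (params$sample_rate < 2 * params$freq_hi)
    stop("sample_rate below the Nyquist rate for the highest grid frequency")
  sr <- params$sample_rate
  nseg <- round(params$chord_dur * sr)
  nch <- params$n_bg_chords
  bg <- numeric(nseg * nch)
  fg <- numeric(nseg * nch)
  for (k in seq_len(nch)) {
    idx <- (k - 1L) * nseg + seq_len(nseg)
    for (f in stim$chords[[k]]) bg[idx] <- bg[idx] + tone_segment(f, params)
    for (f in stim$figure[[k]]) fg[idx] <- fg[idx] + tone_segment(f, params)
  }
  rms <- function(x) sqrt(mean(x ^ 2))
  gain <- if (rms(fg) > 0) 10 ^ (tmr_db / 20) * rms(bg) / rms(fg) else 0
  wave <- bg + gain * fg
  if (normalize && max(abs(wave)) > 0) wave <- 0.9 * wave / max(abs(wave))
  stim$waveform <- wave
  stim$tmr_db <- tmr_db
  stim$figure_gain <- gain
  stim
}

#' Chord manifest of an SFG stimulus
#'
#' @param stim an `"sfg_stimulus"`.
#' @return A data frame with one row per tone: `chord` (0-based index),
#'   `freq_hz`, `is_figure`, `in_gap`.
#' @export
chord_manifest <- function(stim) {
  gap_idx <- stim$gap_onset + seq_len(stim$params$gap_chords) - 1L
  rows <- lapply(seq_along(stim$chords), function(k) {
    i <- k - 1L
    fr <- c(stim$chords[[k]], stim$figure[[k]])
    if (!length(fr)) return(NULL)
    data.frame(chord = i, freq_hz = fr,
               is_figure = rep(c(FALSE, TRUE),
                               c(length(stim$chords[[k]]),
                                 length(stim$figure[[k]]))),
               in_gap = i %in% gap_idx)
  })
  do.call(rbind, rows)
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal canonical RIFF/WAVE writer (mono, 16-bit PCM).  Values are
#' clipped to \[-1, 1\] before quantization.
#'
#' @param stim an `"sfg_stimulus"` with a synthesized waveform, or a plain
#'   numeric vector.
#' @param path output file path.
#' @param sample_rate sample rate in Hz; taken from the stimulus when a
#'   stimulus object is given.
#' @return Invisibly, the path.
#' @export
write_wav <- function(stim, path, sample_rate = NULL) {
  if (inherits(stim, "sfg_stimulus")) {
    if (is.null(stim$waveform)) stop("synthesize the waveform first")
    wave <- stim$waveform
    sample_rate <- stim$params$sample_rate
  } else {
    wave <- as.numeric(stim)
    if (is.null(sample_rate)) stop("sample_rate required for a raw waveform")
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return List with `wave` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || !nzchar(id)) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM supported")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
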