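test_that("frequency grid is logarithmic with 1/24-octave spacing", {
  g <- build_frequency_grid(sfg_params())
  expect_equal(g[1], 179)
  expect_true(all(abs(diff(log2(g)) - 1 / 24) < 1e-12))
  expect_lte(g[length(g)], 7246)
  # enumeration oracle: multiply up from the lower bound until the upper
  # bound is exceeded
  f <- 179; cnt <- 1L
  while (f * 2 ^ (1 / 24) <= 7246) { f <- f * 2 ^ (1 / 24); cnt <- cnt + 1L }
  expect_equal(length(g), cnt)
  expect_equal(length(g), 129)
  expect_error(build_frequency_grid(sfg_params(freq_lo = 8000)),
               "bounds|below")
})

test_that("stimulus structure: figure span, gaps, tone counts", {
  p <- sfg_params()
  for (seed in 1:8) {
    gap_fig <- seed %% 2 == 0
    st <- sample_stimulus(p, gap_in_figure = gap_fig, seed = seed)
    expect_length(st$chords, 62)
    nfig <- vapply(st$figure, length, 0L)
    # figure occupies chords 10..51 (0-based), minus 4 gap chords when the
    # gap is in the figure
    expect_true(all(nfig[1:10] == 0))
    expect_true(all(nfig[53:62] == 0))
    expect_equal(sum(nfig > 0), if (gap_fig) 42 - 4 else 42)
    # figure frequencies identical in every figure-bearing chord
    for (k in which(nfig > 0))
      expect_equal(sort(st$figure[[k]]), st$figure_freqs)
    # background tone counts within 5..15 outside background-gap chords
    nbg <- vapply(st$chords, length, 0L)
    gap_idx <- st$gap_onset + seq_len(p$gap_chords)   # 1-based chords
    if (gap_fig) {
      expect_true(all(nbg >= 5 & nbg <= 15))
    } else {
      expect_true(all(nbg[-gap_idx] >= 5 & nbg[-gap_idx] <= 15))
      expect_true(all(nbg[gap_idx] >= 5 - 3 & nbg[gap_idx] <= 15 - 3))
    }
    # gap inside the figure interval
    expect_gte(st$gap_onset, 20)
    expect_lte(st$gap_onset + p$gap_chords, 52)
    # grid closure
    grid <- build_frequency_grid(p)
    expect_true(all(unlist(st$chords) %in% grid))
    expect_true(all(st$figure_freqs %in% grid))
  }
})

test_that("exactly 12 tone slots are removed per stimulus in either gap condition", {
  p <- sfg_params()
  for (seed in 1:10) {
    fig <- sample_stimulus(p, gap_in_figure = TRUE, seed = seed)
    bg <- sample_stimulus(p, gap_in_figure = FALSE, seed = seed + 100)
    # figure gap: 4 chords x 3 figure tones missing
    missing_fig <- 42 * 3 - sum(vapply(fig$figure, length, 0L))
    expect_equal(missing_fig, 12)
    # background gap: removal confined to 4 consecutive chords inside the
    # figure interval, figure intact
    expect_equal(sum(vapply(bg$figure, length, 0L)), 42 * 3)
    gap_idx <- bg$gap_onset + seq_len(p$gap_chords)
    expect_true(all(gap_idx >= 21 & gap_idx <= 52))
  }
})

test_that("degenerate figure (n_fig = 0) leaves background-only stimulus", {
  st <- sample_stimulus(sfg_params(n_fig = 0), gap_in_figure = TRUE,
                        seed = 3)
  expect_true(all(vapply(st$figure, length, 0L) == 0))
  nbg <- vapply(st$chords, length, 0L)
  expect_true(all(nbg >= 5 & nbg <= 15))
})

test_that("waveform duration, TMR scaling, and spectral content", {
  p <- sfg_params(sample_rate = 16000, freq_hi = 7246)
  st <- sample_stimulus(p, gap_in_figure = FALSE, seed = 5)
  st <- synthesize_waveform(st, tmr_db = 0, normalize = FALSE)
  expect_length(st$waveform, round(62 * 0.05 * 16000))
  expect_equal(length(st$waveform) / 16000, 3.1)

  # 0 dB with equal per-class RMS: per-tone amplitudes equal means the
  # figure gain equals 1 when figure and background have equal summed RMS;
  # check the realized RMS ratio instead, which is the defined contract
  sep <- function(stim, tmr) {
    s <- synthesize_waveform(stim, tmr_db = tmr, normalize = FALSE)
    bgonly <- stim
    bgonly$figure <- lapply(bgonly$figure, function(x) numeric(0))
    bg <- synthesize_waveform(bgonly, tmr_db = tmr, normalize = FALSE)
    fig <- s$waveform - bg$waveform
    20 * log10(sqrt(mean(fig ^ 2)) / sqrt(mean(bg$waveform ^ 2)))
  }
  expect_lt(abs(sep(st, 0) - 0), 0.1)
  expect_lt(abs(sep(st, -6) - (-6)), 0.1)

  # spectrum of a figure-bearing segment peaks at the figure frequencies
  st0 <- synthesize_waveform(st, tmr_db = 12, normalize = FALSE)
  seg <- st0$waveform[(20 * 800 + 1):(30 * 800)]   # chords 20..29 (0-based)
  sp <- Mod(stats::fft(seg)) ^ 2
  freqs <- (seq_along(sp) - 1) * 16000 / length(sp)
  half <- freqs <= 8000
  for (ff in st$figure_freqs) {
    band <- which(half & abs(freqs - ff) < 20)
    near <- which(half & abs(freqs - ff) < 200)
    expect_gt(max(sp[band]), stats::median(sp[near]))
  }
})

test_that("WAV round trip preserves samples, rate, and clipping guard", {
  p <- sfg_params(sample_rate = 8000, freq_hi = 3500)
  st <- sample_stimulus(p, gap_in_figure = TRUE, seed = 2)
  st <- synthesize_waveform(st, tmr_db = 3)
  expect_lte(max(abs(st$waveform)), 1)
  path <- tempfile(fileext = ".wav")
  write_wav(st, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 8000)
  expect_length(back$wave, length(st$waveform))
  expect_lt(max(abs(back$wave - st$waveform)), 1 / 32000)
  unlink(path)
})

test_that("chord manifest indexes every tone with figure and gap flags", {
  st <- sample_stimulus(sfg_params(), gap_in_figure = TRUE, seed = 7)
  man <- chord_manifest(st)
  expect_equal(sum(man$is_figure), 38 * 3)
  expect_equal(sort(unique(man$chord)), 0:61)
  expect_equal(sum(man$in_gap & man$is_figure), 0)
})
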