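cfg <- stim_config()

test_that("fixed figures repeat the same components over 42 chords", {
  set.seed(1)
  fig <- build_fixed_figure(cfg)
  expect_length(fig$chords, 42)
  expect_length(fig$chords[[1]], 3)
  for (ch in fig$chords) expect_identical(ch, fig$chords[[1]])
  expect_true(all(fig$chords[[1]] >= 180 & fig$chords[[1]] <= 7246))

  deg <- build_fixed_figure(stim_config(coherence = 1))
  expect_length(deg$chords[[1]], 1)
})

test_that("fixed-figure frequencies are log-uniform over the ground range", {
  set.seed(2)
  f <- unlist(replicate(1000, build_fixed_figure(cfg)$chords[[1]],
                        simplify = FALSE))
  ks <- suppressWarnings(
    ks.test(log(f), "punif", log(180), log(7246)))
  expect_gt(ks$p.value, 0.01)
})

test_that("insert_gap empties exactly gap_chords chords inside the margins", {
  set.seed(3)
  fig <- insert_gap(build_fixed_figure(cfg), 6, cfg)
  n_with <- sum(vapply(fig$chords, length, 1L) > 0)
  expect_equal(n_with, 36)
  expect_gte(fig$gap["start"] - 1, 5)                       # leading margin
  expect_gte(42 - (fig$gap["start"] + 6 - 1), 5)            # trailing margin

  expect_identical(insert_gap(fig, 0, cfg)$chords, fig$chords)
  short <- build_fixed_figure(stim_config(n_chords_fixed = 12))
  expect_error(insert_gap(short, 6, cfg), "too short")
})

test_that("gap positions are uniform over the admissible window", {
  set.seed(4)
  starts <- replicate(3000,
    insert_gap(build_fixed_figure(cfg), 6, cfg)$gap[["start"]])
  tab <- table(factor(starts, levels = 6:32))   # 27 admissible starts
  expect_equal(sort(unique(starts)), 6:32)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("dynamic figures are harmonic stacks checked against the mask", {
  fig <- build_dynamic_figure(rep(100, 15), c(2, 3, 4), mask_max = 3623)
  for (ch in fig$chords) expect_equal(ch, c(200, 300, 400))

  ident <- build_dynamic_figure(c(150, 160, 170), 1, mask_max = 7246)
  expect_equal(unlist(ident$chords), c(150, 160, 170))

  # arithmetic oracle: 30 * 250 = 7500 > 7246
  expect_error(
    build_dynamic_figure(rep(250, 15), c(5, 10, 20, 30), mask_max = 7246),
    "exceeds mask")
})

test_that("ground tracks stay inside their range with the configured density", {
  set.seed(5)
  gr <- build_ground(42, cfg, cfg$ground_range_high)
  expect_length(gr$chords, 42)
  dens <- vapply(gr$chords, length, 1L)
  expect_true(all(dens >= 9 & dens <= 21))
  f <- unlist(gr$chords)
  expect_true(all(f >= 180 & f <= 7246))

  one <- build_ground(5, stim_config(ground_density = c(1, 1)))
  expect_true(all(vapply(one$chords, length, 1L) == 1))

  # log-uniform median oracle: median ~ geometric mean of the range
  set.seed(6)
  many <- unlist(build_ground(6000, cfg, c(90, 3623))$chords)
  expect_gt(length(many), 5e4)
  expect_lt(abs(median(many) / sqrt(90 * 3623) - 1), 0.02)
})

test_that("rendering produces the right duration, peak and ramp envelope", {
  set.seed(7)
  fig <- insert_gap(build_fixed_figure(cfg), 6, cfg)
  gr <- build_ground(42, cfg)
  st <- render_stimulus(fig, gr, snr_db = 6, cfg)
  expect_equal(length(st$samples), 42 * 0.050 * 44100)     # 92610 samples
  expect_equal(max(abs(st$samples)), 0.95)
  expect_equal(st$meta$n_chords, 42)

  # raised-cosine ramp: RMS of the 10 ms ramp relative to the steady part
  # is sqrt(mean(env^2)) with env = (1-cos)/2, i.e. sqrt(3/8)
  one <- afgtools:::render_track(list(1000), amp = 1, cfg)
  spc <- 2205; nr <- 441
  rms <- function(x) sqrt(mean(x^2))
  ratio <- rms(one[1:nr]) / rms(one[(nr + 1):(spc - nr)])
  expect_lt(abs(ratio - sqrt(3 / 8)), 0.02)
  # envelope rises monotonically over the onset ramp
  peaks <- vapply(split(abs(one[1:440]), rep(1:5, each = 88)), max, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("snr governs per-tone amplitudes and figure energy monotonically", {
  # at 0 dB figure and ground tones have equal amplitude by definition
  expect_equal(10^(0 / 20), 1)
  set.seed(8)
  fig <- build_fixed_figure(cfg)
  rms <- vapply(c(-10, 0, 10, 20), function(snr)
    sqrt(mean(afgtools:::render_track(fig$chords, 10^(snr / 20), cfg)^2)), 0)
  expect_true(all(diff(rms) > 0))
})

test_that("figure components dominate the spectrum at high SNR", {
  set.seed(9)
  # fixed figure with well-separated components so spectral peaks are
  # unambiguous (random draws can place two components within one lobe)
  fig <- afgtools:::new_figure_track(rep(list(c(523, 1847, 4101)), 42),
                                     variant = "fixed")
  gr <- build_ground(42, cfg)
  st <- render_stimulus(fig, gr, snr_db = 20, cfg)
  # FFT-peak oracle on a mid-stimulus chord
  spc <- 2205
  x <- st$samples[(10 * spc + 1):(11 * spc)]
  spec <- abs(fft(x))[1:(spc / 2)]
  bin <- 44100 / spc                                      # 20 Hz
  ord <- order(spec, decreasing = TRUE)
  peaks <- c()
  for (k in ord) {
    fk <- (k - 1) * bin
    if (!length(peaks) || all(abs(peaks - fk) > 3 * bin)) peaks <- c(peaks, fk)
    if (length(peaks) == 3) break
  }
  for (f0 in fig$chords[[1]])
    expect_lt(min(abs(peaks - f0)), bin)
})

test_that("the ground continues through the figure gap", {
  set.seed(10)
  fig <- insert_gap(build_fixed_figure(cfg), 6, cfg)
  gr <- build_ground(42, cfg)
  expect_true(all(vapply(gr$chords, length, 1L) >= 1))
  st <- render_stimulus(fig, gr, 0, cfg)
  spc <- 2205
  gap_idx <- fig$gap[["start"]]
  gap_chord <- st$samples[((gap_idx - 1) * spc + 1):(gap_idx * spc)]
  expect_gt(sqrt(mean(gap_chord^2)), 0.01)   # audible ground inside the gap
})

test_that("pattern pairs are length-matched and differ only when asked", {
  set.seed(11)
  same <- make_pattern_pair(same = TRUE, variant = "dynamic_low", cfg = cfg)
  expect_equal(same$first$meta$n_chords, same$second$meta$n_chords)

  diffp <- make_pattern_pair(same = FALSE, variant = "dynamic_high", cfg = cfg)
  expect_equal(diffp$first$meta$n_chords, diffp$second$meta$n_chords)

  ns <- replicate(100, make_pattern_pair(
    same = TRUE, variant = "dynamic_low", cfg = cfg)$first$meta$n_chords)
  expect_true(all(ns >= 15 & ns <= 29))

  expect_error(make_pattern_pair(contours = list(synth_contour(16)),
                                 same = FALSE, cfg = cfg),
               "at least two")
})

test_that("dynamic-figure components respect the variant frequency caps", {
  set.seed(12)
  for (i in 1:20) {
    p <- make_pattern_pair(same = FALSE, variant = "dynamic_low", cfg = cfg)
    # with the default contour stats the low variant tops out at 4 * 295.44
    expect_true(p$first$meta$n_chords >= 15)
  }
  # a contour pushed to the top of the high range must raise
  hot <- list(pitch_contour(rep(250, 100)), pitch_contour(rep(250, 100)))
  expect_error(
    make_pattern_pair(hot, same = TRUE, variant = "dynamic_high", cfg = cfg),
    "exceeds mask")
})

test_that("rendering is deterministic under a fixed seed", {
  gen <- function() {
    set.seed(99)
    fig <- insert_gap(build_fixed_figure(cfg), 6, cfg)
    render_stimulus(fig, build_ground(42, cfg), 3, cfg)$samples
  }
  expect_identical(gen(), gen())
})

test_that("WAV files round-trip within one quantization step", {
  set.seed(13)
  fig <- build_fixed_figure(cfg)
  st <- render_stimulus(fig, build_ground(42, cfg), 0, cfg)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(st, path)
  back <- read_wav(path)
  expect_lt(max(abs(back$samples - st$samples)), 2^-15)
  expect_identical(back$sample_rate, st$sample_rate)
  expect_identical(back$snr_db, st$snr_db)       # sidecar restores SNR exactly
  expect_equal(back$meta$n_chords, 42)
})

test_that("trials concatenate the two intervals with the commanded silence", {
  set.seed(14)
  fig <- build_fixed_figure(cfg)
  a <- render_stimulus(fig, build_ground(42, cfg), 0, cfg)
  b <- render_stimulus(insert_gap(fig, 6, cfg), build_ground(42, cfg), 0, cfg)
  tr <- render_trial(a, b, isi_ms = cfg$isi_ms_fixed)
  isi_n <- 0.400 * 44100
  expect_length(tr, 2 * 92610 + isi_n)
  expect_true(all(tr[92610 + seq_len(isi_n)] == 0))
})
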