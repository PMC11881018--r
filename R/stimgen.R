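# Figure/ground track construction and audio rendering for the three AFG
# stimulus variants (fixed, dynamic-low, dynamic-high).

#' Stimulus configuration
#'
#' Holds every stimulus parameter of the AFG battery. Defaults encode the
#' battery's design: 50 ms chords gated with 10 ms raised-cosine ramps; the
#' fixed-frequency figure is 42 chords long with coherence 3 and a 6-chord
#' gap; ground tone clouds are log-uniform over 180-7246 Hz (fixed and
#' dynamic-high) or 90-3623 Hz (dynamic-low, half the band for better
#' masking); dynamic figures are harmonic complexes at multiples {2,3,4}
#' (low) or {5,10,20,30} (high) of the sentence F0; inter-stimulus intervals
#' are 400 ms (fixed task) and 200 ms (dynamic tasks).
#'
#' @param chord_ms chord duration (ms).
#' @param ramp_ms raised-cosine on/off ramp duration (ms).
#' @param sample_rate audio sample rate (Hz).
#' @param coherence figure components per chord in the fixed variant.
#' @param n_chords_fixed fixed-figure length in chords.
#' @param gap_chords gap length in chords (fixed task).
#' @param ground_range_high,ground_range_low ground frequency ranges (Hz).
#' @param multipliers_low,multipliers_high harmonic multipliers of F0.
#' @param ground_density integer range (min, max); tones per ground chord are
#'   drawn uniformly from it, independently per chord.
#' @param dynamic_chord_range admissible dynamic-figure lengths in chords.
#' @param isi_ms_fixed,isi_ms_dynamic inter-stimulus interval within a trial (ms).
#' @param gap_margin_chords minimum figure chords flanking a gap.
#' @param peak peak-normalization target for rendered audio.
#' @return A `stim_config` list.
#' @export
stim_config <- function(chord_ms = 50, ramp_ms = 10, sample_rate = 44100,
                        coherence = 3, n_chords_fixed = 42, gap_chords = 6,
                        ground_range_high = c(180, 7246),
                        ground_range_low = c(90, 3623),
                        multipliers_low = c(2, 3, 4),
                        multipliers_high = c(5, 10, 20, 30),
                        ground_density = c(9, 21),
                        dynamic_chord_range = c(15, 29),
                        isi_ms_fixed = 400, isi_ms_dynamic = 200,
                        gap_margin_chords = 5, peak = 0.95) {
  stopifnot(chord_ms > 0, ramp_ms >= 0, 2 * ramp_ms <= chord_ms,
            sample_rate > 0, coherence >= 1,
            ground_range_high[1] < ground_range_high[2],
            ground_range_low[1] < ground_range_low[2],
            !is.unsorted(multipliers_low), !is.unsorted(multipliers_high),
            ground_density[1] >= 1, ground_density[1] <= ground_density[2],
            peak > 0, peak <= 1)
  structure(as.list(environment()), class = "stim_config")
}

# log-uniform draw on [lo, hi]
rlunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

new_figure_track <- function(chords, variant, gap = NULL, f0 = NULL) {
  structure(list(chords = chords, gap = gap, variant = variant, f0 = f0),
            class = "figure_track")
}

#' @export
print.figure_track <- function(x, ...) {
  cat(sprintf("<figure_track> %s, %d chords", x$variant, length(x$chords)))
  if (!is.null(x$gap))
    cat(sprintf(", gap @ chord %d (%d chords)", x$gap[1], x$gap[2]))
  cat("\n")
  invisible(x)
}

#' Build a fixed-frequency figure track
#'
#' Draws `coherence` distinct frequencies log-uniformly from the high ground
#' range and repeats them in every chord: the temporally coherent figure of
#' the gap-discrimination task.
#'
#' @param cfg a [stim_config()].
#' @return A `figure_track` (variant `"fixed"`, no gap yet).
#' @export
#' @examples
#' set.seed(1)
#' fig <- build_fixed_figure()
#' length(fig$chords); fig$chords[[1]]
build_fixed_figure <- function(cfg = stim_config()) {
  stopifnot(inherits(cfg, "stim_config"), cfg$coherence <= 20)
  repeat {
    f <- rlunif(cfg$coherence, cfg$ground_range_high[1], cfg$ground_range_high[2])
    if (!anyDuplicated(f)) break
  }
  new_figure_track(rep(list(sort(f)), cfg$n_chords_fixed), variant = "fixed")
}

#' Insert a figure gap
#'
#' Silences the figure components in `gap_chords` consecutive chords at a
#' position drawn uniformly over all starts leaving at least
#' `cfg$gap_margin_chords` figure chords on each side. Ground tracks are
#' unaffected: the tone cloud continues through the gap.
#'
#' @param figure a `figure_track`.
#' @param gap_chords gap length in chords.
#' @param cfg a [stim_config()] (margin).
#' @return The figure with `gap` metadata and emptied gap chords.
#' @export
insert_gap <- function(figure, gap_chords = 6, cfg = stim_config()) {
  stopifnot(inherits(figure, "figure_track"), gap_chords >= 0)
  if (gap_chords == 0) return(figure)
  n <- length(figure$chords)
  m <- cfg$gap_margin_chords
  first <- m + 1
  last <- n - gap_chords - m + 1
  if (last < first) stop("figure too short to host the gap with margins")
  start <- sample(first:last, 1)
  for (i in start:(start + gap_chords - 1)) figure$chords[[i]] <- numeric(0)
  figure$gap <- c(start = start, length = gap_chords)
  figure
}

#' Build a harmonic dynamic figure from per-chord F0 values
#'
#' Each chord carries the harmonic complex `multipliers * F0[i]`, so the
#' figure follows the pitch trajectory of a sentence. Errors if any component
#' exceeds `mask_max`, the top of the masking ground range (the battery's
#' design check that figures stay inside the ground band).
#'
#' @param f0_series a `chord_f0` from [chunk_to_chords()], or a numeric vector
#'   of per-chord F0 values in Hz.
#' @param multipliers harmonic multipliers (e.g. `c(2, 3, 4)`).
#' @param mask_max maximum admissible component frequency (Hz).
#' @param variant label, `"dynamic_low"` or `"dynamic_high"`.
#' @return A `figure_track`.
#' @export
#' @examples
#' build_dynamic_figure(rep(100, 15), c(2, 3, 4), 3623)$chords[[1]]
build_dynamic_figure <- function(f0_series, multipliers, mask_max,
                                 variant = "dynamic_low") {
  f0 <- if (inherits(f0_series, "chord_f0")) f0_series$f0_per_chord else f0_series
  stopifnot(is.numeric(f0), length(f0) >= 1, all(f0 > 0),
            all(multipliers > 0))
  top <- max(f0) * max(multipliers)
  if (top > mask_max)
    stop(sprintf("figure exceeds mask: top component %.1f Hz > %.1f Hz",
                 top, mask_max))
  chords <- lapply(f0, function(f) sort(multipliers * f))
  new_figure_track(chords, variant = variant, f0 = f0)
}

#' Build a stochastic ground track
#'
#' The ground is a tone cloud: each chord holds an independently drawn number
#' of tones (uniform integer over `cfg$ground_density`) with frequencies
#' i.i.d. log-uniform over `range`.
#'
#' @param n_chords chord count (match the figure).
#' @param cfg a [stim_config()].
#' @param range frequency range (Hz), e.g. `cfg$ground_range_high`.
#' @return A `ground_track`: list of per-chord frequency vectors.
#' @export
build_ground <- function(n_chords, cfg = stim_config(),
                         range = cfg$ground_range_high) {
  stopifnot(n_chords >= 1, range[1] < range[2])
  dens <- sample(cfg$ground_density[1]:cfg$ground_density[2], n_chords,
                 replace = TRUE)
  chords <- lapply(dens, function(k) rlunif(k, range[1], range[2]))
  structure(list(chords = chords, range = range), class = "ground_track")
}

# Render a list of per-chord frequency vectors as gated sinusoids.
# Returns the raw (un-normalized) sample vector; amp is per-tone amplitude.
render_track <- function(chords, amp, cfg) {
  spc <- round(cfg$chord_ms / 1000 * cfg$sample_rate)
  nr <- round(cfg$ramp_ms / 1000 * cfg$sample_rate)
  env <- rep(1, spc)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- ramp
    env[spc - nr + seq_len(nr)] <- rev(ramp)
  }
  tt <- (seq_len(spc) - 1) / cfg$sample_rate
  out <- numeric(spc * length(chords))
  for (i in seq_along(chords)) {
    f <- chords[[i]]
    if (length(f) == 0) next
    w <- sin(2 * pi * outer(tt, f))          # spc x n_tones
    out[(i - 1) * spc + seq_len(spc)] <- env * (w %*% rep(amp, length(f)))
  }
  out
}

#' Render a figure-ground stimulus to audio
#'
#' Every figure and ground component becomes a `chord_ms` pure tone gated with
#' `ramp_ms` raised-cosine on/off ramps. Ground tones have unit per-tone
#' amplitude; figure tones have amplitude `10^(snr_db/20)`, so the commanded
#' SNR is the per-tone figure-to-ground amplitude ratio in dB (independent of
#' ground density). The mixture is peak-normalized to `cfg$peak`.
#'
#' @param figure a `figure_track`.
#' @param ground a `ground_track` with the same chord count.
#' @param snr_db commanded figure-to-ground SNR in dB.
#' @param cfg a [stim_config()].
#' @return A `rendered_stimulus`: `samples` in `[-1, 1]`, `sample_rate`,
#'   `snr_db` and `meta` (variant, chord count, gap).
#' @export
render_stimulus <- function(figure, ground, snr_db, cfg = stim_config()) {
  stopifnot(inherits(figure, "figure_track"), inherits(ground, "ground_track"))
  if (length(figure$chords) != length(ground$chords))
    stop("figure and ground chord counts differ")
  amp_fig <- 10^(snr_db / 20)
  x <- render_track(figure$chords, amp_fig, cfg) +
       render_track(ground$chords, 1, cfg)
  x <- x / max(abs(x)) * cfg$peak
  structure(list(samples = x, sample_rate = cfg$sample_rate, snr_db = snr_db,
                 meta = list(variant = figure$variant,
                             n_chords = length(figure$chords),
                             gap = figure$gap)),
            class = "rendered_stimulus")
}

#' @export
print.rendered_stimulus <- function(x, ...) {
  cat(sprintf("<rendered_stimulus> %s, %d chords, %.3f s @ %d Hz, SNR %+g dB\n",
              x$meta$variant, x$meta$n_chords,
              length(x$samples) / x$sample_rate, x$sample_rate, x$snr_db))
  invisible(x)
}

#' Build a same/different dynamic-figure stimulus pair
#'
#' Constructs the two intervals of one pattern-discrimination trial: two
#' dynamic figure-ground stimuli of identical chord count whose figures either
#' share one F0 series (`same = TRUE`) or are built from different pitch
#' trajectories truncated to matched length. Each interval gets an
#' independently drawn ground tailored to its figure's range.
#'
#' @param contours list of gap-free [pitch_contour()]s (>= 2 when
#'   `same = FALSE`); defaults to freshly synthesized contours of a random
#'   admissible length.
#' @param same logical: same figure pattern in both intervals?
#' @param variant `"dynamic_low"` or `"dynamic_high"`.
#' @param snr_db commanded SNR for both intervals.
#' @param cfg a [stim_config()].
#' @return List of two `rendered_stimulus` objects plus `same` flag.
#' @export
make_pattern_pair <- function(contours = NULL, same, variant = "dynamic_low",
                              snr_db = 12, cfg = stim_config()) {
  stopifnot(is.logical(same), variant %in% c("dynamic_low", "dynamic_high"))
  if (is.null(contours)) {
    n_chords <- sample(cfg$dynamic_chord_range[1]:cfg$dynamic_chord_range[2], 1)
    contours <- list(synth_contour(n_chords), synth_contour(n_chords))
  }
  if (!same && length(contours) < 2)
    stop("need at least two distinct contours for a different-pattern trial")
  mult <- if (variant == "dynamic_low") cfg$multipliers_low else cfg$multipliers_high
  grange <- if (variant == "dynamic_low") cfg$ground_range_low else cfg$ground_range_high
  s1 <- chunk_to_chords(contours[[1]], cfg$chord_ms)
  n1 <- length(s1$f0_per_chord)
  if (same) {
    s2 <- s1
  } else {
    s2 <- chunk_to_chords(contours[[2]], cfg$chord_ms)
    n <- min(n1, length(s2$f0_per_chord))
    if (n < 1) stop("no matched-length contour pair available")
    s1$f0_per_chord <- s1$f0_per_chord[seq_len(n)]
    s2$f0_per_chord <- s2$f0_per_chord[seq_len(n)]
    if (all(s1$f0_per_chord == s2$f0_per_chord))
      stop("no matched-length contour pair available: patterns identical")
  }
  figs <- lapply(list(s1, s2), build_dynamic_figure, multipliers = mult,
                 mask_max = grange[2], variant = variant)
  stims <- lapply(figs, function(fg)
    render_stimulus(fg, build_ground(length(fg$chords), cfg, grange), snr_db, cfg))
  list(first = stims[[1]], second = stims[[2]], same = same)
}

#' Concatenate the two intervals of a trial with an inter-stimulus interval
#'
#' @param a,b `rendered_stimulus` intervals.
#' @param isi_ms silent inter-stimulus interval in ms.
#' @return A numeric sample vector `a | silence | b`.
#' @export
render_trial <- function(a, b, isi_ms) {
  stopifnot(a$sample_rate == b$sample_rate)
  c(a$samples, numeric(round(isi_ms / 1000 * a$sample_rate)), b$samples)
}
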