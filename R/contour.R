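# Pitch-contour processing: cleaning, conjoining, smoothing and chunking of
# speech F0 trajectories, plus a calibrated synthetic-contour generator.

#' Construct a pitch contour
#'
#' A pitch contour holds one fundamental-frequency (F0) value per analysis
#' frame on a regular grid (default 100 frames/s, i.e. 10 ms frames, matching
#' common speech pitch-tracker output). Unvoiced frames are `NA`.
#'
#' @param f0 numeric vector of F0 values in Hz; `NA` (or 0, converted to `NA`)
#'   marks unvoiced frames.
#' @param frame_rate frames per second (> 0), default 100.
#' @param source_id optional opaque label (e.g. sentence id).
#' @return An object of class `pitch_contour`.
#' @export
#' @examples
#' pc <- pitch_contour(c(120, NA, 130, 128), source_id = "demo")
#' pc
pitch_contour <- function(f0, frame_rate = 100, source_id = NULL) {
  stopifnot(is.numeric(f0), length(f0) >= 1, is.numeric(frame_rate),
            frame_rate > 0)
  f0 <- as.numeric(f0)
  f0[!is.na(f0) & f0 == 0] <- NA_real_
  if (any(!is.na(f0) & f0 < 0)) stop("F0 values must be positive")
  structure(list(f0 = f0, frame_rate = frame_rate, source_id = source_id),
            class = "pitch_contour")
}

#' @export
print.pitch_contour <- function(x, ...) {
  nv <- sum(!is.na(x$f0))
  cat(sprintf("<pitch_contour> %d frames @ %g/s (%.2f s), %d voiced (%.0f%%)",
              length(x$f0), x$frame_rate, length(x$f0) / x$frame_rate,
              nv, 100 * nv / length(x$f0)))
  if (!is.null(x$source_id)) cat(sprintf(" [%s]", x$source_id))
  cat("\n")
  invisible(x)
}

#' @export
length.pitch_contour <- function(x) length(x$f0)

#' Reference contour statistics
#'
#' Summary statistics of the speech F0 corpus the synthetic generator emulates:
#' male-speaker matrix-sentence contours spanning 74.94-295.44 Hz with mean
#' 131.59 Hz and s.d. 15.61 Hz, sampled at 100 frames/s with unvoiced gaps.
#'
#' @param f_min,f_max lower/upper bound of the F0 range in Hz.
#' @param mean,sd population mean and standard deviation in Hz.
#' @param gap_fraction proportion of unvoiced frames in raw contours.
#' @return A `contour_stats` list.
#' @export
contour_stats <- function(f_min = 74.94, f_max = 295.44, mean = 131.59,
                          sd = 15.61, gap_fraction = 0.25) {
  stopifnot(f_min < f_max, f_min <= mean, mean <= f_max, sd >= 0,
            gap_fraction >= 0, gap_fraction < 1)
  structure(list(f_min = f_min, f_max = f_max, mean = mean, sd = sd,
                 gap_fraction = gap_fraction), class = "contour_stats")
}

#' Remove pitch-tracker artifacts outside a plausible F0 band
#'
#' Periodicity analysis of speech can produce spurious very-low-frequency
#' values and octave-error spikes; frames outside `(lo, hi)` are marked
#' unvoiced. The frame grid is unchanged.
#'
#' @param contour a [pitch_contour()].
#' @param lo,hi exclusive band edges in Hz (defaults 10 and 300).
#' @return A `pitch_contour` with out-of-band frames set to `NA`.
#' @export
#' @examples
#' pc <- pitch_contour(c(120, 8, 350, 130))
#' strip_artifacts(pc)$f0
strip_artifacts <- function(contour, lo = 10, hi = 300) {
  stopifnot(inherits(contour, "pitch_contour"), lo < hi)
  f0 <- contour$f0
  f0[!is.na(f0) & (f0 <= lo | f0 >= hi)] <- NA_real_
  if (all(is.na(f0))) stop("empty contour: no voiced frame survives the band")
  pitch_contour(f0, contour$frame_rate, contour$source_id)
}

#' Conjoin voiced segments of a contour
#'
#' Deletes unvoiced gaps and concatenates the voiced runs onto a contiguous
#' frame grid, so listeners cannot exploit natural speech pauses. Gaps shorter
#' than `gap_bridge_ms` (isolated dropped frames inside a voiced run) are
#' bridged by linear interpolation instead of deletion; leading/trailing gaps
#' are always deleted.
#'
#' @param contour a [pitch_contour()].
#' @param gap_bridge_ms gaps strictly shorter than this are interpolated
#'   (default 50 ms).
#' @return A gap-free `pitch_contour`.
#' @export
conjoin_voiced <- function(contour, gap_bridge_ms = 50) {
  stopifnot(inherits(contour, "pitch_contour"))
  f0 <- contour$f0
  if (all(is.na(f0))) stop("empty contour: all frames unvoiced")
  voiced <- which(!is.na(f0))
  f0 <- f0[min(voiced):max(voiced)]          # trim edge gaps
  r <- rle(is.na(f0))
  bridge_frames <- gap_bridge_ms / 1000 * contour$frame_rate
  # interpolate short interior gaps, keep long ones for deletion
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  short_gap <- r$values & r$lengths < bridge_frames
  for (k in which(short_gap)) {
    idx <- starts[k]:ends[k]
    f0[idx] <- approx(x = c(starts[k] - 1, ends[k] + 1),
                      y = f0[c(starts[k] - 1, ends[k] + 1)], xout = idx)$y
  }
  f0 <- f0[!is.na(f0)]                        # delete remaining (long) gaps
  pitch_contour(f0, contour$frame_rate, contour$source_id)
}

# Kaiser-window FIR low-pass design for a given stopband attenuation.
# Transition band is 15% of the cutoff; signal::kaiserord gives order + beta.
design_lowpass <- function(cutoff, stop_atten, fs) {
  dev <- 10^(-stop_atten / 20)
  ko <- signal::kaiserord(c(cutoff, 1.15 * cutoff), c(1, 0), c(dev, dev), fs)
  n <- ko$n + (ko$n %% 2)                    # even order -> symmetric taps
  signal::fir1(n, ko$Wc[1], type = "low", window = signal::kaiser(n + 1, ko$beta))
}

#' Smooth a conjoined contour by detrend + low-pass filtering
#'
#' Removes the seam spikes introduced by conjoining: the contour is demeaned
#' and linearly detrended (least squares), upsampled by linear interpolation to
#' `upsample_rate`, low-pass filtered with a minimum-order Kaiser-window FIR
#' (stopband attenuation `stop_atten`, cutoff `cutoff`, applied zero-phase),
#' decimated back to the frame grid, and the trend and mean are restored.
#'
#' The stated cutoff only bites on the upsampled signal: at 100 frames/s the
#' contour itself carries no energy anywhere near 2 kHz, so the filter's role
#' is to remove the broadband edges of interpolation spikes.
#'
#' @param contour gap-free [pitch_contour()].
#' @param cutoff low-pass cutoff in Hz (default 2000).
#' @param stop_atten stopband attenuation in dB (default 60).
#' @param upsample_rate rate the contour is interpolated to before filtering
#'   (default 44100 Hz).
#' @return A smoothed `pitch_contour` with identical duration and mean.
#' @export
smooth_contour <- function(contour, cutoff = 2000, stop_atten = 60,
                           upsample_rate = 44100) {
  stopifnot(inherits(contour, "pitch_contour"), cutoff < upsample_rate / 2)
  x <- contour$f0
  if (anyNA(x)) stop("smooth_contour requires a gap-free contour; see conjoin_voiced()")
  n <- length(x)
  tt <- (seq_len(n) - 1) / contour$frame_rate
  trend <- lm(x ~ tt)
  resid <- as.numeric(trend$residuals)
  tu <- seq(0, tt[n], by = 1 / upsample_rate)
  xu <- approx(tt, resid, xout = tu)$y
  h <- design_lowpass(cutoff, stop_atten, upsample_rate)
  if (length(xu) <= 3 * (length(h) - 1))
    stop("contour too short for the filter warm-up")
  # odd-reflection padding suppresses the zero-state edge transients of the
  # forward-backward pass
  np <- length(h)
  nx <- length(xu)
  xp <- c(2 * xu[1] - xu[(np + 1):2], xu, 2 * xu[nx] - xu[(nx - 1):(nx - np)])
  yp <- signal::filtfilt(as.numeric(h), 1, xp)
  yu <- yp[np + seq_len(nx)]
  y <- approx(tu, yu, xout = tt)$y
  # re-centre: the filter is DC-unity but edge transients can leave a tiny
  # offset; the least-squares residual has exactly zero mean, so restore it
  y <- y - mean(y)
  y <- y + as.numeric(predict(trend))
  pitch_contour(y, contour$frame_rate, contour$source_id)
}

#' Average a contour into per-chord F0 values
#'
#' Groups the frame-level F0 values into consecutive `chord_ms` windows and
#' takes the arithmetic mean of each window, yielding one figure element per
#' chord. A trailing partial window shorter than `chord_ms / 2` is dropped,
#' otherwise it is averaged as a final chord.
#'
#' @param contour gap-free [pitch_contour()].
#' @param chord_ms chord duration in ms (default 50).
#' @return A `chord_f0` object: list with `f0_per_chord` (Hz) and `chord_ms`.
#' @export
#' @examples
#' pc <- pitch_contour(rep(100, 100))
#' chunk_to_chords(pc)$f0_per_chord
chunk_to_chords <- function(contour, chord_ms = 50) {
  stopifnot(inherits(contour, "pitch_contour"), chord_ms > 0)
  x <- contour$f0
  if (anyNA(x)) stop("chunk_to_chords requires a gap-free contour")
  fpc <- chord_ms / 1000 * contour$frame_rate   # frames per chord
  if (length(x) < fpc) stop("contour shorter than one chord")
  n_full <- floor(length(x) / fpc)
  idx <- ceiling(seq_along(x) / fpc)
  means <- tapply(x, idx, mean)
  n_rem <- length(x) - n_full * fpc
  keep <- if (n_rem >= fpc / 2) n_full + 1 else n_full
  structure(list(f0_per_chord = as.numeric(means[seq_len(keep)]),
                 chord_ms = chord_ms),
            class = "chord_f0")
}

#' Generate a synthetic speech-like pitch contour
#'
#' Emulates pitch contours of read matrix sentences: a slowly varying random
#' process (three random-phase sinusoids with modulation rates drawn from
#' 0.5-3 Hz) superimposed on a per-sentence mean and a mild downward
#' declination of 10% of the mean over the sentence, clipped to
#' `[stats$f_min, stats$f_max]`. Gap-free by construction. Uses the session
#' RNG; wrap in [set.seed()] for reproducibility.
#'
#' @param n_chords length of the contour in 50 ms chords (15-29 unless
#'   `enforce_range = FALSE`).
#' @param stats a [contour_stats()] target distribution.
#' @param frame_rate frames per second (default 100).
#' @param chord_ms chord duration defining total length (default 50).
#' @param enforce_range require `n_chords` within 15-29.
#' @return A gap-free `pitch_contour`.
#' @export
#' @examples
#' set.seed(1)
#' range(synth_contour(20)$f0)
synth_contour <- function(n_chords, stats = contour_stats(), frame_rate = 100,
                          chord_ms = 50, enforce_range = TRUE) {
  stopifnot(inherits(stats, "contour_stats"))
  if (stats$f_min >= stats$f_max) stop("infeasible stats: f_min >= f_max")
  if (enforce_range && (n_chords < 15 || n_chords > 29))
    stop("n_chords must lie in [15, 29] (set enforce_range = FALSE to override)")
  n <- round(n_chords * chord_ms / 1000 * frame_rate)
  tt <- (seq_len(n) - 1) / frame_rate
  dur <- n / frame_rate
  m <- rnorm(1, stats$mean, 6)               # between-sentence mean spread
  decl <- 0.1 * stats$mean                   # downward declination, centred
  # within-sentence sd budget: total sd^2 = between (6^2) + declination
  # (decl^2/12) + sinusoids (3 a^2 / 2)
  v_sin <- max(stats$sd^2 - 36 - decl^2 / 12, 1)
  a <- sqrt(2 * v_sin / 3)
  fmod <- runif(3, 0.5, 3)
  ph <- runif(3, 0, 2 * pi)
  wave <- rowSums(sapply(1:3, function(k) a * sin(2 * pi * fmod[k] * tt + ph[k])))
  f0 <- m + wave - decl * (tt / dur - 0.5)
  pitch_contour(clamp(f0, stats$f_min, stats$f_max), frame_rate,
                source_id = "synthetic")
}

#' Read / write pitch-contour CSV files
#'
#' Plain-text interchange format: header `time_s,f0_hz`, one row per frame,
#' unvoiced frames as an empty field. Values round-trip exactly (written with
#' 17 significant digits).
#'
#' @param contour a [pitch_contour()].
#' @param path file path.
#' @return `read_contour_csv` returns a `pitch_contour`; `write_contour_csv`
#'   returns `path` invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "pitch_contour"))
  tt <- (seq_along(contour$f0) - 1) / contour$frame_rate
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  writeLines(c("time_s,f0_hz",
               paste(fmt(tt), fmt(contour$f0), sep = ",")), path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  d <- read.csv(path, colClasses = c("numeric", "numeric"))
  if (!identical(names(d), c("time_s", "f0_hz")))
    stop("contour CSV must have header time_s,f0_hz")
  if (nrow(d) < 2) stop("contour CSV needs at least two frames")
  fr <- 1 / median(diff(d$time_s))
  pitch_contour(d$f0_hz, frame_rate = round(fr, 6), source_id = path)
}
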