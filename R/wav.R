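# Minimal 16-bit PCM mono WAV I/O (RIFF) plus a JSON metadata sidecar.

#' Write a rendered stimulus to a 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16-bit PCM. A JSON
#' sidecar `<path>.json` records the stimulus metadata (variant, chord count,
#' gap location, commanded SNR) so every artifact is self-describing.
#'
#' @param stim a `rendered_stimulus` from [render_stimulus()].
#' @param path output `.wav` path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(stim, path, sidecar = TRUE) {
  stopifnot(inherits(stim, "rendered_stimulus"))
  pcm <- as.integer(round(clamp(stim$samples, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL); w_int(36L + n_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_int(16L, 4)
  w_int(1L, 2); w_int(1L, 2)                       # PCM, mono
  w_int(stim$sample_rate, 4)
  w_int(stim$sample_rate * 2L, 4)                  # byte rate
  w_int(2L, 2); w_int(16L, 2)                      # block align, bits
  writeChar("data", con, eos = NULL); w_int(n_bytes, 4)
  writeBin(pcm, con, size = 2, endian = "little")
  if (sidecar)
    jsonlite::write_json(
      c(list(sample_rate = stim$sample_rate, snr_db = stim$snr_db,
             n_samples = length(stim$samples)), stim$meta),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by [write_wav()]
#'
#' @param path `.wav` path; if `<path>.json` exists its metadata (including
#'   the commanded SNR) is restored.
#' @return A `rendered_stimulus`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_int <- function(size, signed = TRUE)
    readBin(con, "integer", n = 1, size = size, endian = "little",
            signed = signed)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file")
  r_int(4)
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  sr <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- r_int(4)
    if (id == "fmt ") {
      fmt <- r_int(2); nch <- r_int(2); sr <- r_int(4)
      r_int(4); r_int(2); bits <- r_int(2)
      if (fmt != 1 || nch != 1 || bits != 16)
        stop("only 16-bit PCM mono supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      samples <- readBin(con, "integer", n = sz / 2, size = 2,
                         endian = "little", signed = TRUE) / 32767
      break
    } else readBin(con, "raw", sz)
  }
  if (is.null(sr) || is.null(samples)) stop("malformed WAV file")
  meta <- list(); snr <- NA_real_
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    snr <- as.numeric(meta$snr_db)
    meta <- meta[setdiff(names(meta), c("sample_rate", "snr_db", "n_samples"))]
  }
  structure(list(samples = samples, sample_rate = as.numeric(sr), snr_db = snr,
                 meta = meta),
            class = "rendered_stimulus")
}
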