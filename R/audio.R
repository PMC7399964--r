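#' Audio signal container
#'
#' A mono waveform with its sampling rate. Samples are dimensionless
#' amplitudes in \[-1, 1\].
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\], all finite.
#' @param sample_rate sampling rate in Hz (positive integer-valued scalar).
#' @return an object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @export
#' @examples
#' s <- audio_signal(sin(2 * pi * 200 * seq(0, 1, by = 1/8000)), 8000)
#' duration_s(s)
audio_signal <- function(samples, sample_rate) {
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (sample_rate != round(sample_rate)) stop("sample_rate must be an integer number of Hz")
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples))) stop("samples must all be finite")
  if (length(samples) && max(abs(samples)) > 1 + 1e-9)
    stop("samples must lie in [-1, 1]")
  structure(list(samples = samples, sample_rate = as.integer(sample_rate)),
            class = "audio_signal")
}

#' @rdname audio_signal
#' @param x an `audio_signal`.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %.3f s @ %d Hz, %d samples, peak %.3f>\n",
              duration_s(x), x$sample_rate, length(x$samples),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

# --- minimal RIFF/WAVE I/O -------------------------------------------------
# Supports the formats the pipeline emits and consumes: PCM 16-bit and IEEE
# float 32-bit, mono or stereo (stereo is downmixed by channel averaging).

#' Read a WAV file
#'
#' Reads PCM 16-bit or IEEE-float 32-bit RIFF/WAVE files. Stereo input is
#' downmixed to mono by averaging the channels.
#'
#' @param path path to a .wav file.
#' @return an [audio_signal].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate     = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))  # skip unknown chunk (padded)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bits)")
  }
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels, byrow = TRUE))
  }
  audio_signal(pmin(1, pmax(-1, x)), fmt$rate)
}

#' Write a WAV file
#'
#' Writes an [audio_signal] as mono PCM 16-bit RIFF/WAVE.
#'
#' @param signal an [audio_signal].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(signal$samples * 32767))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")           # PCM, mono
  writeBin(signal$sample_rate, con, 4, endian = "little")
  writeBin(signal$sample_rate * 2L, con, 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")          # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
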