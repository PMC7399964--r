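#' Utterance segmentation parameters
#'
#' Controls the speech/silence state machine. A frame is "speech" when its
#' peak absolute amplitude reaches `amplitude_threshold` (fraction of full
#' scale); an utterance opens once speech persists for `onset_hold_s` and
#' closes once silence persists for `offset_hold_s`.
#'
#' @param amplitude_threshold speech/silence amplitude threshold, fraction of
#'   full scale in (0, 1). Default 0.02.
#' @param onset_hold_s seconds of sustained speech required to open an
#'   utterance. Default 0.1.
#' @param offset_hold_s seconds of sustained silence required to close an
#'   utterance. Default 0.35; silences shorter than this (breaths, stop
#'   closures) are bridged.
#' @param frame_s analysis hop of the state machine in seconds. Default 0.01.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(amplitude_threshold = 0.02, onset_hold_s = 0.1,
                                offset_hold_s = 0.35, frame_s = 0.01) {
  check_scalar(amplitude_threshold, "amplitude_threshold", positive = TRUE)
  if (amplitude_threshold >= 1) stop("amplitude_threshold must be < 1")
  check_scalar(onset_hold_s, "onset_hold_s", positive = TRUE)
  check_scalar(offset_hold_s, "offset_hold_s", positive = TRUE)
  check_scalar(frame_s, "frame_s", positive = TRUE)
  structure(list(amplitude_threshold = amplitude_threshold,
                 onset_hold_s = onset_hold_s, offset_hold_s = offset_hold_s,
                 frame_s = frame_s),
            class = "segmentation_params")
}

# per-frame peak absolute amplitude; a trailing partial frame counts as a frame
frame_peaks <- function(samples, frame_len) {
  n <- length(samples)
  if (n == 0L) return(numeric(0))
  n_full <- n %/% frame_len
  peaks <- if (n_full > 0) {
    m <- matrix(abs(samples[seq_len(n_full * frame_len)]), nrow = frame_len)
    apply(m, 2, max)
  } else numeric(0)
  if (n > n_full * frame_len)
    peaks <- c(peaks, max(abs(samples[(n_full * frame_len + 1):n])))
  peaks
}

#' Segment an audio signal into utterances
#'
#' Runs the speech/silence state machine over per-frame peak amplitudes. An
#' utterance is a maximal speech interval: it opens at the start of a speech
#' run that persists at least `onset_hold_s`, bridges silences shorter than
#' `offset_hold_s`, closes at the last speech frame before a silence run of at
#' least `offset_hold_s`, and a trailing open utterance is closed at signal
#' end. Intervals are half-open `[start_s, end_s)`, frame-quantized.
#'
#' @param signal an [audio_signal].
#' @param params a [segmentation_params].
#' @return a data.frame of class `utterance_table` with columns `index`,
#'   `start_s`, `end_s`, sorted and non-overlapping. An empty or all-silent
#'   signal yields zero rows.
#' @export
#' @examples
#' sr <- 8000
#' x <- c(numeric(sr), 0.5 * sin(2 * pi * 200 * seq_len(2 * sr) / sr), numeric(sr))
#' segment_utterances(audio_signal(x, sr),
#'                    segmentation_params(amplitude_threshold = 0.1))
segment_utterances <- function(signal, params = segmentation_params()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(params, "segmentation_params"))
  frame_len <- max(1L, round(params$frame_s * signal$sample_rate))
  frame_s <- frame_len / signal$sample_rate
  speech <- frame_peaks(signal$samples, frame_len) >= params$amplitude_threshold
  n_on <- max(1L, ceiling(params$onset_hold_s / frame_s))
  n_off <- max(1L, ceiling(params$offset_hold_s / frame_s))

  utts <- list()
  if (any(speech)) {
    runs <- rle(speech)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    open <- FALSE
    u_start <- NA_integer_
    last_speech_end <- NA_integer_
    for (i in seq_along(runs$lengths)) {
      if (runs$values[i]) {
        if (!open && runs$lengths[i] >= n_on) {
          open <- TRUE
          u_start <- starts[i]
        }
        if (open) last_speech_end <- ends[i]
      } else if (open && runs$lengths[i] >= n_off) {
        utts[[length(utts) + 1L]] <- c(u_start, last_speech_end)
        open <- FALSE
      }
    }
    if (open) utts[[length(utts) + 1L]] <- c(u_start, last_speech_end)
  }

  out <- if (length(utts)) {
    m <- do.call(rbind, utts)
    data.frame(index = seq_len(nrow(m)),
               start_s = (m[, 1] - 1L) * frame_s,
               end_s = m[, 2] * frame_s)
  } else {
    data.frame(index = integer(0), start_s = numeric(0), end_s = numeric(0))
  }
  class(out) <- c("utterance_table", "data.frame")
  attr(out, "frame_s") <- frame_s
  out
}

#' @export
print.utterance_table <- function(x, ...) {
  cat(sprintf("Utterances: %d (total speech %.2f s)\n",
              nrow(x), sum(x$end_s - x$start_s)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
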