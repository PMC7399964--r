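#' Fundamental-frequency track for one utterance
#'
#' Short-time normalized-autocorrelation pitch tracking. For each analysis
#' frame (hop `frame_s`, window about 2.5 periods of `f0_min` centred on the
#' frame) the lag in `[sample_rate/f0_max, sample_rate/f0_min]` with the
#' highest normalized cross-correlation is taken; the peak is refined by
#' parabolic interpolation. Frames whose peak correlation falls below
#' `voicing_threshold`, or whose energy is negligible, are unvoiced (f0 = 0).
#'
#' @param signal an [audio_signal].
#' @param utt one utterance: a list/row with `start_s` and `end_s`, lying
#'   inside the signal.
#' @param f0_min,f0_max pitch search band in Hz, `0 < f0_min < f0_max <
#'   sample_rate/2`. Defaults 60 and 400, covering adult conversational
#'   speech.
#' @param frame_s analysis hop in seconds (default 0.01).
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.3).
#' @return an object of class `f0_track`: list with `times_s` (frame centres,
#'   seconds from signal start), `f0_hz` (0 where unvoiced) and `voiced`
#'   (logical), all the same length.
#' @export
extract_f0 <- function(signal, utt, f0_min = 60, f0_max = 400, frame_s = 0.01,
                       voicing_threshold = 0.3) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  if (!(f0_min > 0 && f0_min < f0_max && f0_max < sr / 2))
    stop("need 0 < f0_min < f0_max < sample_rate/2")
  bounds <- utt_bounds(signal, utt)
  centers <- frame_centers(bounds, sr, frame_s)
  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- ceiling(sr / f0_min)
  half_win <- ceiling(2.5 * sr / f0_min / 2) + lag_max %/% 2

  f0 <- numeric(length(centers))
  voiced <- logical(length(centers))
  for (i in seq_along(centers)) {
    c_idx <- round(centers[i] * sr)
    a <- max(bounds[1], c_idx - half_win)
    b <- min(bounds[2], c_idx + half_win)
    x <- signal$samples[a:b]
    x <- x - mean(x)
    n <- length(x)
    if (n < lag_min + 8L || sqrt(mean(x^2)) < 1e-5) next
    k_hi <- min(lag_max, n - 8L)
    if (k_hi <= lag_min) next
    lags <- lag_min:k_hi
    e_full <- cumsum(x^2)
    nc <- vapply(lags, function(k) {
      m <- n - k
      num <- sum(x[1:m] * x[(k + 1):n])
      den <- sqrt(e_full[m] * (e_full[n] - e_full[k]))
      if (den <= 0) 0 else num / den
    }, numeric(1))
    best <- max(nc)
    if (best < voicing_threshold) next
    # integer multiples of the true period correlate equally well, so take
    # the shortest *local maximum* within tolerance of the peak, not the
    # global argmax (and not a band-edge lag that merely clears the bar)
    is_peak <- c(FALSE, diff(sign(diff(nc))) < 0, FALSE)
    cand <- which(is_peak & nc >= 0.95 * best)
    j <- if (length(cand)) cand[1L] else which.max(nc)
    k <- lags[j]
    # parabolic refinement of the correlation peak
    if (j > 1L && j < length(lags)) {
      denom <- nc[j - 1L] - 2 * nc[j] + nc[j + 1L]
      if (denom < 0) k <- k + 0.5 * (nc[j - 1L] - nc[j + 1L]) / denom
    }
    hz <- sr / k
    f0[i] <- min(f0_max, max(f0_min, hz))
    voiced[i] <- TRUE
  }
  structure(list(times_s = centers, f0_hz = f0, voiced = voiced),
            class = "f0_track")
}

#' @export
print.f0_track <- function(x, ...) {
  v <- x$f0_hz[x$voiced]
  cat(sprintf("<f0_track: %d frames, %.0f%% voiced%s>\n",
              length(x$times_s), 100 * mean(x$voiced),
              if (length(v)) sprintf(", f0 %.0f-%.0f Hz", min(v), max(v)) else ""))
  invisible(x)
}

#' Per-frame RMS intensity envelope of an utterance
#'
#' Root-mean-square amplitude per analysis frame, on the same framing (hop
#' and frame centres) as [extract_f0].
#'
#' @inheritParams extract_f0
#' @return numeric vector of non-negative per-frame RMS values.
#' @export
intensity_envelope <- function(signal, utt, frame_s = 0.01) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  bounds <- utt_bounds(signal, utt)
  centers <- frame_centers(bounds, sr, frame_s)
  half <- frame_s / 2
  vapply(centers, function(ct) {
    a <- max(bounds[1], round((ct - half) * sr) + 1L)
    b <- min(bounds[2], round((ct + half) * sr))
    if (b < a) return(0)
    sqrt(mean(signal$samples[a:b]^2))
  }, numeric(1))
}

# sample index bounds [first, last] of an utterance, validated against signal
utt_bounds <- function(signal, utt) {
  start_s <- utt$start_s
  end_s <- utt$end_s
  if (is.null(start_s) || is.null(end_s)) stop("utterance needs start_s and end_s")
  n <- length(signal$samples)
  sr <- signal$sample_rate
  if (start_s < 0 || end_s * sr > n + 0.5 || end_s <= start_s)
    stop("utterance [", start_s, ", ", end_s, ") outside signal bounds")
  c(max(1L, round(start_s * sr) + 1L), min(n, round(end_s * sr)))
}

# frame centres (seconds from signal start) for hop frame_s over the utterance;
# bounds are sample indices, sr converts them to seconds
frame_centers <- function(bounds, sr, frame_s) {
  check_scalar(frame_s, "frame_s", positive = TRUE)
  start_s <- (bounds[1] - 1L) / sr
  dur <- (bounds[2] - bounds[1] + 1L) / sr
  n_frames <- max(1L, floor(dur / frame_s))
  start_s + (seq_len(n_frames) - 0.5) * frame_s
}
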