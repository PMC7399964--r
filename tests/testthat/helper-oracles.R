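# Independent oracles and signal builders shared across the test files.
# These deliberately re-derive results by the most literal route available
# (per-frame scans, filter-and-aggregate loops) so they stay independent of
# the package's vectorized implementations.

# Brute-force utterance segmentation: a per-frame state scan with explicit
# speech/silence counters, one frame at a time.
oracle_segment <- function(samples, sr, threshold, onset_s, offset_s, frame_s) {
  frame_len <- max(1, round(frame_s * sr))
  fs <- frame_len / sr
  n_frames <- ceiling(length(samples) / frame_len)
  speech <- logical(n_frames)
  for (i in seq_len(n_frames)) {
    a <- (i - 1) * frame_len + 1
    b <- min(length(samples), i * frame_len)
    speech[i] <- max(abs(samples[a:b])) >= threshold
  }
  n_on <- max(1, ceiling(onset_s / fs))
  n_off <- max(1, ceiling(offset_s / fs))
  out <- NULL
  in_utt <- FALSE
  run_speech <- 0; run_silence <- 0
  run_start <- NA; last_speech <- NA; utt_start <- NA
  for (i in seq_len(n_frames)) {
    if (speech[i]) {
      if (run_speech == 0) run_start <- i
      run_speech <- run_speech + 1
      run_silence <- 0
      if (!in_utt && run_speech >= n_on) {
        in_utt <- TRUE
        utt_start <- run_start
      }
      if (in_utt) last_speech <- i
    } else {
      run_silence <- run_silence + 1
      run_speech <- 0
      if (in_utt && run_silence >= n_off) {
        out <- rbind(out, c(utt_start, last_speech))
        in_utt <- FALSE
      }
    }
  }
  if (in_utt) out <- rbind(out, c(utt_start, last_speech))
  if (is.null(out))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  data.frame(start_s = (out[, 1] - 1) * fs, end_s = out[, 2] * fs)
}

# Brute-force mental activity: filter the window, then aggregate, per point.
oracle_mental_activity <- function(times, values, k = 1, window_days = 14,
                                   min_points = 5) {
  out <- NULL
  for (i in seq_along(times)) {
    sel <- times > times[i] - window_days * 86400 & times <= times[i]
    if (sum(sel) < min_points) next
    v <- values[sel]
    out <- rbind(out, data.frame(
      time = times[i], value = min(1, max(0, mean(v) - k * sd(v))),
      n_window_points = sum(sel), window_mean = mean(v), window_sd = sd(v)))
  }
  out
}

# Random burst-structured test signal: alternating silence and constant-
# amplitude segments, at a low sample rate to keep the suite quick.
random_burst_signal <- function(sr = 1000, max_dur_s = 6) {
  total <- 0
  x <- numeric(0)
  while (total < runif(1, 1, max_dur_s)) {
    dur <- runif(1, 0.02, 0.8)
    n <- round(dur * sr)
    seg <- if (runif(1) < 0.45) numeric(n) else
      runif(1, 0.02, 0.9) * sin(2 * pi * 150 * seq_len(n) / sr)
    x <- c(x, seg)
    total <- total + dur
  }
  audio_signal(pmin(1, pmax(-1, x)), sr)
}

# Pure tone / linear chirp builders used by the pitch and affect tests.
tone_signal <- function(freq, dur_s = 1, amp = 0.5, sr = 8000) {
  audio_signal(amp * sin(2 * pi * freq * seq_len(round(dur_s * sr)) / sr), sr)
}

chirp_signal <- function(f0, f1, dur_s = 1, amp = 0.5, sr = 8000) {
  n <- round(dur_s * sr)
  f <- f0 + (f1 - f0) * (seq_len(n) - 1) / n
  audio_signal(amp * sin(2 * pi * cumsum(f) / sr), sr)
}

whole_utt <- function(signal) list(start_s = 0, end_s = duration_s(signal))

# Zeroed prosodic feature set (the logistic layer's origin).
zero_features <- function() {
  structure(list(f0_mean = 0, f0_sd = 0, f0_slope = 0, f0_range = 0,
                 voiced_fraction = 0, rms_mean = 0, rms_cv = 0,
                 duration_s = 1e-9),
            class = "prosodic_features")
}

# A 100-point sample constructed so that (i) its mean is exactly 0 and its
# sample sd exactly 1, and (ii) exactly 20 points fall in each of the 5
# equal-probability bins of N(0, 1): chi-square must be exactly 0.
exact_gof_sample <- function() {
  a <- 0.1
  b <- 0.5
  c_ <- sqrt((99 - 20 * a^2 - 40 * b^2) / 40)  # solves sample var = 1
  stopifnot(c_ > qnorm(0.8))
  c(rep(-c_, 20), rep(-b, 20), rep(-a, 10), rep(a, 10), rep(b, 20), rep(c_, 20))
}

# Small deterministic call/user/BDI fixture tables.
make_users <- function(ids, sex = "man", region = "Kanto",
                       consent = "2016-01-01T00:00:00Z") {
  data.frame(user_id = ids, consent_at = as.POSIXct(consent, tz = "UTC"),
             sex = sex, age = 30, region = region,
             hist_depression = FALSE, present_depression = FALSE)
}

make_calls <- function(user_id, days, vitality, duration_s = 60,
                       n_utterances = 8,
                       origin = as.POSIXct("2016-01-01T00:00:00Z", tz = "UTC")) {
  if (length(days) == 0L)
    return(data.frame(user_id = character(0), call_start = origin[0],
                      duration_s = numeric(0), vitality = numeric(0),
                      valid = logical(0), n_utterances = integer(0)))
  valid <- duration_s >= 10 & n_utterances >= 6
  data.frame(user_id = user_id, call_start = origin + days * 86400,
             duration_s = duration_s,
             vitality = ifelse(valid, vitality, NA_real_),
             valid = valid, n_utterances = n_utterances)
}
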