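#' Prosodic features of one utterance
#'
#' Summary statistics of the F0 track and intensity envelope that feed the
#' affect layer. F0 statistics are computed over voiced frames only and are
#' all zero when no frame is voiced; RMS statistics use all frames.
#'
#' @param track an [f0_track][extract_f0].
#' @param envelope per-frame RMS vector from [intensity_envelope], same
#'   framing as `track`.
#' @param duration_s utterance duration in seconds.
#' @return an object of class `prosodic_features`: named list with
#'   `f0_mean`, `f0_sd`, `f0_slope` (least-squares Hz/s over voiced frames),
#'   `f0_range`, `voiced_fraction`, `rms_mean`, `rms_cv`, `duration_s`.
#' @export
compute_features <- function(track, envelope, duration_s) {
  stopifnot(inherits(track, "f0_track"))
  if (length(envelope) != length(track$f0_hz))
    stop("envelope and f0 track must share framing (",
         length(envelope), " vs ", length(track$f0_hz), " frames)")
  check_scalar(duration_s, "duration_s", positive = TRUE)
  v <- track$voiced
  if (any(v)) {
    f0 <- track$f0_hz[v]
    t <- track$times_s[v]
    slope <- if (length(f0) >= 2 && stats::sd(t) > 0)
      unname(stats::coef(stats::lm.fit(cbind(1, t), f0))[2]) else 0
    feat <- list(f0_mean = mean(f0),
                 f0_sd = if (length(f0) >= 2) stats::sd(f0) else 0,
                 f0_slope = slope,
                 f0_range = max(f0) - min(f0))
  } else {
    feat <- list(f0_mean = 0, f0_sd = 0, f0_slope = 0, f0_range = 0)
  }
  feat$voiced_fraction <- mean(v)
  feat$rms_mean <- mean(envelope)
  feat$rms_cv <- if (feat$rms_mean > 0 && length(envelope) >= 2)
    stats::sd(envelope) / feat$rms_mean else 0
  feat$duration_s <- duration_s
  structure(feat, class = "prosodic_features")
}

FEATURE_NAMES <- c("f0_mean", "f0_sd", "f0_slope", "f0_range",
                   "voiced_fraction", "rms_mean", "rms_cv", "duration_s")
EMOTION_NAMES <- c("calmness", "anger", "joy", "sorrow", "excitement")

#' Affect-layer configuration
#'
#' Parameters of the prosody-to-emotion stand-in model and of the vitality
#' combination. Each emotion intensity is
#' `plogis(bias + sum(weights * features/scales))`; raw features are divided
#' by fixed reference scales so the weights are comparable across features,
#' and zeroed features yield exactly `plogis(bias)`. The default weights are
#' chosen so that flat, low-variability, moderate-energy speech reads as calm,
#' low-energy monotone speech as sorrowful, and energetic variable speech as
#' joyful/excited; per-utterance vitality then centres near 0.55 for neutral
#' lively speech.
#'
#' @param emotion_weights named list (one entry per emotion) of lists with a
#'   `bias` and named feature `weights`.
#' @param feature_scales named numeric vector of reference scales dividing
#'   each raw feature.
#' @param w_pos,w_neg,w_exc vitality combination weights for the positive
#'   (joy + calmness), negative (sorrow + anger) and arousal (excitement)
#'   channels. Defaults 0.4, 0.4, 0.1.
#' @return an object of class `affect_config`.
#' @export
affect_config <- function(emotion_weights = NULL, feature_scales = NULL,
                          w_pos = 0.4, w_neg = 0.4, w_exc = 0.1) {
  if (is.null(feature_scales))
    feature_scales <- c(f0_mean = 200, f0_sd = 25, f0_slope = 100,
                        f0_range = 80, voiced_fraction = 1, rms_mean = 0.15,
                        rms_cv = 0.5, duration_s = 3)
  if (is.null(emotion_weights)) emotion_weights <- default_emotion_weights()
  stopifnot(setequal(names(feature_scales), FEATURE_NAMES),
            setequal(names(emotion_weights), EMOTION_NAMES))
  for (e in EMOTION_NAMES) {
    w <- emotion_weights[[e]]
    if (!is.finite(w$bias) || !all(is.finite(unlist(w$weights))))
      stop("non-finite weights for ", e)
    if (!all(names(w$weights) %in% FEATURE_NAMES))
      stop("unknown feature in weights for ", e)
  }
  for (w in c(w_pos, w_neg, w_exc)) check_scalar(w, "vitality weight")
  structure(list(emotion_weights = emotion_weights,
                 feature_scales = feature_scales[FEATURE_NAMES],
                 w_pos = w_pos, w_neg = w_neg, w_exc = w_exc),
            class = "affect_config")
}

default_emotion_weights <- function() {
  list(
    calmness   = list(bias = 0.6,  weights = c(f0_sd = -1.2, rms_cv = -0.8,
                      voiced_fraction = 3.0, rms_mean = -0.2, f0_slope = -0.2)),
    anger      = list(bias = -2.4, weights = c(rms_mean = 1.0, rms_cv = 0.8,
                      f0_sd = 0.6, f0_mean = -1.0, f0_slope = -0.4)),
    joy        = list(bias = -4.65, weights = c(rms_mean = 0.8, f0_mean = 2.0,
                      f0_sd = 0.5, f0_slope = 0.6, voiced_fraction = 1.5)),
    sorrow     = list(bias = 3.82, weights = c(rms_mean = -1.0, f0_sd = -0.6,
                      f0_mean = -1.667, f0_slope = -0.5, voiced_fraction = -1.5)),
    excitement = list(bias = -4.33, weights = c(rms_mean = 0.9, f0_sd = 1.0,
                      f0_range = 0.5, f0_mean = 1.333)))
}

#' Emotion intensities of one utterance
#'
#' Deterministic logistic mapping from [prosodic features][compute_features]
#' to the five emotion intensities, each in \[0, 1\]. This layer is an
#' explicit documented stand-in for the proprietary voice-sensibility model
#' used by the original system, whose functional form is not public.
#'
#' @param feat a `prosodic_features` object (or named list covering the same
#'   fields).
#' @param cfg an [affect_config].
#' @return named numeric vector of class `emotion_scores` with components
#'   `calmness`, `anger`, `joy`, `sorrow`, `excitement`.
#' @export
score_emotions <- function(feat, cfg = affect_config()) {
  stopifnot(inherits(cfg, "affect_config"))
  x <- unlist(feat[FEATURE_NAMES])
  if (length(x) != length(FEATURE_NAMES) || !all(is.finite(x)))
    stop("features must be finite and complete")
  u <- x / cfg$feature_scales
  out <- vapply(EMOTION_NAMES, function(e) {
    w <- cfg$emotion_weights[[e]]
    stats::plogis(w$bias + sum(w$weights * u[names(w$weights)]))
  }, numeric(1))
  structure(out, class = "emotion_scores")
}

#' @export
print.emotion_scores <- function(x, ...) {
  cat("Emotion intensities:\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-utterance vitality from emotion intensities
#'
#' Combines the five emotion intensities into a single \[0, 1\] score:
#' `clip(0.5 + w_pos*(joy + calmness - 1)/2 - w_neg*(sorrow + anger - 1)/2 +
#' w_exc*(excitement - 0.5), 0, 1)`. At the neutral point (all intensities
#' 0.5) the score is exactly 0.5 for any weights.
#'
#' @param scores an [emotion_scores][score_emotions] vector.
#' @param cfg an [affect_config] supplying `w_pos`, `w_neg`, `w_exc`.
#' @return vitality in \[0, 1\].
#' @export
utterance_vitality <- function(scores, cfg = affect_config()) {
  stopifnot(inherits(cfg, "affect_config"))
  s <- unclass(scores)
  check_unit(unlist(s[EMOTION_NAMES]), "emotion scores")
  v <- 0.5 +
    cfg$w_pos * (s[["joy"]] + s[["calmness"]] - 1) / 2 -
    cfg$w_neg * (s[["sorrow"]] + s[["anger"]] - 1) / 2 +
    cfg$w_exc * (s[["excitement"]] - 0.5)
  min(1, max(0, v))
}

#' Score a whole call from audio
#'
#' Full per-call chain: segmentation, per-utterance F0/intensity, features,
#' emotions, per-utterance vitality, then the call-level vitality (mean over
#' utterances, subject to the validity rules of [call_vitality]).
#'
#' @param signal an [audio_signal].
#' @param seg_params a [segmentation_params].
#' @param cfg an [affect_config].
#' @param f0_min,f0_max,frame_s passed to [extract_f0].
#' @return list with `utterances` (data.frame: index, start_s, end_s,
#'   vitality and the five emotions), `vitality` (call-level, NA when
#'   invalid), and `valid`.
#' @export
score_call <- function(signal, seg_params = segmentation_params(),
                       cfg = affect_config(), f0_min = 60, f0_max = 400,
                       frame_s = 0.01) {
  utts <- segment_utterances(signal, seg_params)
  rows <- lapply(seq_len(nrow(utts)), function(i) {
    u <- utts[i, ]
    track <- extract_f0(signal, u, f0_min, f0_max, frame_s)
    env <- intensity_envelope(signal, u, frame_s)
    feat <- compute_features(track, env, u$end_s - u$start_s)
    emo <- score_emotions(feat, cfg)
    c(vitality = utterance_vitality(emo, cfg), unclass(emo))
  })
  scored <- cbind(as.data.frame(utts),
                  if (length(rows)) as.data.frame(do.call(rbind, rows))
                  else as.data.frame(matrix(numeric(0), 0, 6,
                    dimnames = list(NULL, c("vitality", EMOTION_NAMES)))))
  cv <- call_vitality(scored$vitality, duration_s(signal))
  list(utterances = scored, vitality = cv$vitality, valid = cv$valid)
}

# --- config file round-trip ------------------------------------------------

#' Read / write an affect configuration
#'
#' Plain-text YAML serialization of [affect_config]; `read_affect_config`
#' inverts `write_affect_config` exactly.
#'
#' @param cfg an [affect_config].
#' @param path file path.
#' @return `write_affect_config` returns `path` invisibly;
#'   `read_affect_config` returns an [affect_config].
#' @export
write_affect_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "affect_config"))
  obj <- list(
    feature_scales = as.list(cfg$feature_scales),
    vitality_weights = list(w_pos = cfg$w_pos, w_neg = cfg$w_neg,
                            w_exc = cfg$w_exc),
    emotions = lapply(cfg$emotion_weights, function(w)
      list(bias = w$bias, weights = as.list(w$weights))))
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_affect_config
#' @export
read_affect_config <- function(path) {
  obj <- yaml::read_yaml(path)
  affect_config(
    emotion_weights = lapply(obj$emotions, function(w)
      list(bias = w$bias, weights = unlist(w$weights))),
    feature_scales = unlist(obj$feature_scales),
    w_pos = obj$vitality_weights$w_pos,
    w_neg = obj$vitality_weights$w_neg,
    w_exc = obj$vitality_weights$w_exc)
}
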