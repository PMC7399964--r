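#' Call-level vitality with validity rules
#'
#' The call-level score is the arithmetic mean of the per-utterance vitality
#' values. A call is valid only when it lasted at least 10 seconds and
#' produced at least `min_utterances` scored utterances; otherwise the score
#' is absent (NA) and the call is flagged invalid. Short calls and calls with
#' few utterances give unstable scores, hence the filters.
#'
#' @param utterance_vitalities numeric vector of per-utterance scores in
#'   \[0, 1\].
#' @param duration_s call duration in seconds.
#' @param min_duration_s minimum valid call duration (default 10).
#' @param min_utterances minimum number of scored utterances (default 6).
#' @return list with `vitality` (mean, or NA when invalid) and `valid`.
#' @export
#' @examples
#' call_vitality(rep(0.5, 6), 30)  # valid, 0.5
#' call_vitality(rep(0.5, 5), 30)  # invalid: too few utterances
#' call_vitality(rep(0.5, 6), 9)   # invalid: under 10 s
call_vitality <- function(utterance_vitalities, duration_s,
                          min_duration_s = 10, min_utterances = 6) {
  check_unit(utterance_vitalities, "utterance vitalities")
  if (length(duration_s) != 1L || !is.finite(duration_s) || duration_s < 0)
    stop("duration_s must be a non-negative scalar")
  valid <- duration_s >= min_duration_s &&
    length(utterance_vitalities) >= min_utterances
  list(vitality = if (valid) mean(utterance_vitalities) else NA_real_,
       valid = valid)
}

#' 0-100 display scaling
#'
#' Scores are computed in \[0, 1\] but displayed to users on a 0-100 integer
#' scale: value times 100, rounded half-up.
#'
#' @param value numeric vector in \[0, 1\].
#' @return integer vector in 0-100.
#' @export
#' @examples
#' display_scale(c(0.56, 0.455, 0, 1))  # 56 46 0 100
display_scale <- function(value) {
  check_unit(value, "value")
  as.integer(round_half_up(value * 100))
}

#' Mental activity at one time point
#'
#' The longitudinal index at time `at` summarizes the vitality points in the
#' half-open 14-day window `(at - window_days, at]`: with fewer than
#' `min_points` points it is absent; otherwise
#' `value = clip(mean - k * sd, 0, 1)` where `sd` is the sample standard
#' deviation over the window. The variation penalty `k` (default 1) encodes
#' that erratic vitality is itself a warning sign; two weeks matches the
#' persistence criterion for depressive symptoms.
#'
#' @param history data.frame with columns `time` (POSIXct or ISO-8601
#'   strings) and `value` (vitality in \[0, 1\]) for one user, sorted by
#'   time.
#' @param at timestamp at which to evaluate.
#' @param k variation penalty weight (default 1).
#' @param window_days window length in days (default 14).
#' @param min_points minimum vitality points in the window (default 5).
#' @return NULL when absent, else list with `time`, `value`,
#'   `n_window_points`, `window_mean`, `window_sd`.
#' @export
mental_activity <- function(history, at, k = 1, window_days = 14,
                            min_points = 5) {
  t <- as.numeric(as_utc(history$time))
  if (is.unsorted(t)) stop("history must be sorted by time")
  check_unit(history$value, "vitality values")
  at_n <- as.numeric(as_utc(at))
  in_win <- t > at_n - window_days * DAY_S & t <= at_n
  n <- sum(in_win)
  if (n < min_points) return(NULL)
  v <- history$value[in_win]
  m <- mean(v)
  s <- stats::sd(v)
  list(time = as_utc(at), value = min(1, max(0, m - k * s)),
       n_window_points = n, window_mean = m, window_sd = s)
}

#' Mental-activity series for one user
#'
#' Evaluates [mental_activity] at every vitality point of one user's history,
#' returning the points where the index is defined (at least `min_points`
#' vitality values in the trailing window). Windowed sums are computed with
#' cumulative sums, so long histories stay O(n log n).
#'
#' @inheritParams mental_activity
#' @return data.frame with columns `time`, `value`, `n_window_points`,
#'   `window_mean`, `window_sd` (zero rows when never defined).
#' @export
mental_activity_series <- function(history, k = 1, window_days = 14,
                                   min_points = 5) {
  t <- as.numeric(as_utc(history$time))
  if (is.unsorted(t)) stop("history must be sorted by time")
  check_unit(history$value, "vitality values")
  n <- length(t)
  empty <- data.frame(time = as_utc(numeric(0)), value = numeric(0),
                      n_window_points = integer(0), window_mean = numeric(0),
                      window_sd = numeric(0))
  if (n == 0L) return(empty)
  v <- history$value
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  # first index inside (t_i - window, t_i]: strictly greater than the cutoff
  lo <- findInterval(t - window_days * DAY_S, t) + 1L
  # findInterval counts points <= cutoff; equality with the cutoff must stay
  # outside the half-open window, which is exactly what <= gives us
  cnt <- seq_len(n) - lo + 1L
  keep <- cnt >= min_points
  if (!any(keep)) return(empty)
  i <- which(keep)
  cs0 <- c(0, cs)
  cs20 <- c(0, cs2)
  s1 <- cs0[i + 1L] - cs0[lo[i]]
  s2 <- cs20[i + 1L] - cs20[lo[i]]
  m <- s1 / cnt[i]
  var <- pmax(0, (s2 - s1^2 / cnt[i]) / (cnt[i] - 1L))
  sd <- sqrt(var)
  data.frame(time = as_utc(t[i]), value = pmin(1, pmax(0, m - k * sd)),
             n_window_points = cnt[i], window_mean = m, window_sd = sd)
}

#' Mental-activity points for every user in a call table
#'
#' Convenience wrapper: restricts to valid calls, sorts per user, and stacks
#' each user's [mental_activity_series] with a `user_id` column. Users who
#' never reach `min_points` vitality values in a window contribute no rows.
#'
#' @param calls call table with `user_id`, `call_start`, `vitality`, `valid`.
#' @inheritParams mental_activity
#' @return data.frame with `user_id`, `time`, `value`, `n_window_points`,
#'   `window_mean`, `window_sd`.
#' @export
mental_activity_table <- function(calls, k = 1, window_days = 14,
                                  min_points = 5) {
  valid <- calls[calls$valid & !is.na(calls$vitality), , drop = FALSE]
  valid$call_start <- as_utc(valid$call_start)
  valid <- valid[order(valid$user_id, valid$call_start), , drop = FALSE]
  parts <- lapply(split(valid, valid$user_id, drop = TRUE), function(d) {
    s <- mental_activity_series(data.frame(time = d$call_start,
                                           value = d$vitality),
                                k = k, window_days = window_days,
                                min_points = min_points)
    if (nrow(s) == 0L) return(NULL)
    cbind(user_id = d$user_id[1L], s)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(user_id = character(0), time = as_utc(numeric(0)),
                      value = numeric(0), n_window_points = integer(0),
                      window_mean = numeric(0), window_sd = numeric(0))
  rownames(out) <- NULL
  out
}

#' Days of system use
#'
#' Whole days elapsed from study consent to the most recent analyzed call:
#' the floor of the elapsed time in days, 0 when the user never had a call
#' analyzed or stopped the same day.
#'
#' @param consent_at consent timestamp(s).
#' @param last_call_at timestamp(s) of the most recent analyzed call, NA when
#'   none.
#' @return non-negative integer vector of days used.
#' @export
days_used <- function(consent_at, last_call_at) {
  c0 <- as.numeric(as_utc(consent_at))
  c1 <- as.numeric(as_utc(last_call_at))
  out <- ifelse(is.na(c1), 0, floor((c1 - c0) / DAY_S))
  if (any(out < 0, na.rm = TRUE)) stop("last analyzed call precedes consent")
  as.integer(out)
}

#' Rate-of-continued-use (retention) curve
#'
#' Fraction of users whose days-used reaches each day `d = 0, 1, ...`. The
#' value at `d = 0` is 1 by construction and the curve is monotone
#' non-increasing.
#'
#' @param days integer vector of per-user [days_used] values.
#' @return data.frame of class `retention_curve` with columns `day` and
#'   `fraction`.
#' @export
#' @examples
#' retention_curve(c(0, 5, 10))
retention_curve <- function(days) {
  if (length(days) == 0L) stop("retention_curve needs at least one user")
  if (any(days < 0)) stop("days used must be non-negative")
  d <- 0:(max(days) + 1L)
  out <- data.frame(day = d,
                    fraction = vapply(d, function(k) mean(days >= k), numeric(1)))
  class(out) <- c("retention_curve", "data.frame")
  out
}

#' @export
plot.retention_curve <- function(x, ...) {
  graphics::plot(x$day, x$fraction, type = "s", ylim = c(0, 1),
                 xlab = "days since consent", ylab = "fraction still active",
                 main = "Rate of continued use", ...)
  invisible(x)
}
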