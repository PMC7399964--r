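#' BDI score category
#'
#' Users with a Beck Depression Inventory score below 11 are treated as
#' healthy ("normal"); 11 or above as "abnormal".
#'
#' @param score integer vector of BDI scores in 0-63.
#' @return factor with levels `normal`, `abnormal`.
#' @export
categorize_bdi <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 63))
    stop("BDI scores must lie in [0, 63]")
  factor(ifelse(score < 11, "normal", "abnormal"),
         levels = c("normal", "abnormal"))
}

#' Filter BDI records by completion time
#'
#' Keeps records whose questionnaire completion time falls in
#' `[lo_s, hi_s]` (endpoints inclusive), the band used to drop rushed and
#' abandoned-then-resumed answers. With `mode = "percentile"` the band is
#' instead the central `1 - 2*trim` mass of the observed completion times
#' (default: drop the bottom and top 10%).
#'
#' @param bdi data.frame with a `completion_time_s` column.
#' @param lo_s,hi_s inclusive band in seconds (defaults 80 and 300).
#' @param mode `"band"` (default) or `"percentile"`.
#' @param trim tail mass dropped on each side in percentile mode (default
#'   0.10).
#' @return the filtered data.frame.
#' @export
filter_by_completion_time <- function(bdi, lo_s = 80, hi_s = 300,
                                      mode = c("band", "percentile"),
                                      trim = 0.10) {
  mode <- match.arg(mode)
  if (nrow(bdi) == 0L) return(bdi)
  ct <- bdi$completion_time_s
  if (mode == "percentile") {
    q <- stats::quantile(ct, c(trim, 1 - trim), names = FALSE, type = 7)
    lo_s <- q[1]; hi_s <- q[2]
  }
  if (lo_s >= hi_s) stop("lo_s must be < hi_s")
  bdi[ct >= lo_s & ct <= hi_s, , drop = FALSE]
}

#' Build the call analysis dataset
#'
#' Applies the study filters to a call table: keeps calls with a valid
#' vitality (at least 10 s and at least 6 utterances), then drops every call
#' of users for whom no valid mental-activity point can ever be computed
#' (fewer than `min_points` valid vitality scores in some 14-day window at
#' any time). Each retained call is annotated with the user's sex and region.
#' Calls referencing unknown users are reported, not fatal.
#'
#' @param calls data.frame with columns `user_id`, `call_start`, `duration_s`,
#'   `vitality`, `valid`, `n_utterances` (the call CSV dialect).
#' @param users data.frame with at least `user_id`, `sex`, `region`.
#' @param k,window_days,min_points mental-activity parameters, see
#'   [mental_activity_series].
#' @return the filtered call data.frame (sorted by user and time, with `sex`
#'   and `region` columns), with attribute `rejects`: a data.frame listing
#'   calls dropped for unknown user ids.
#' @export
build_call_dataset <- function(calls, users, k = 1, window_days = 14,
                               min_points = 5) {
  req <- c("user_id", "call_start", "duration_s", "vitality", "valid")
  if (!all(req %in% names(calls)))
    stop("calls must have columns ", paste(req, collapse = ", "))
  calls$call_start <- as_utc(calls$call_start)
  orphan <- !(calls$user_id %in% users$user_id)
  rejects <- calls[orphan, , drop = FALSE]
  kept <- calls[!orphan & calls$valid & !is.na(calls$vitality), , drop = FALSE]
  kept <- kept[order(kept$user_id, kept$call_start), , drop = FALSE]

  # users who attain at least one valid mental-activity point
  attains <- vapply(split(kept, kept$user_id, drop = TRUE), function(d) {
    nrow(mental_activity_series(
      data.frame(time = d$call_start, value = d$vitality),
      k = k, window_days = window_days, min_points = min_points)) > 0
  }, logical(1))
  kept <- kept[kept$user_id %in% names(attains)[attains], , drop = FALSE]

  idx <- match(kept$user_id, users$user_id)
  kept$sex <- users$sex[idx]
  kept$region <- if ("region" %in% names(users)) users$region[idx] else NA
  rownames(kept) <- NULL
  attr(kept, "rejects") <- rejects
  kept
}

#' Build the user analysis dataset
#'
#' One row per user, anchored to the initial BDI questionnaire: the first
#' valid call vitality strictly after the initial BDI time, and the
#' mental-activity point nearest in the configured direction within
#' `window_days` of the BDI time. Users missing either quantity are excluded.
#'
#' @param calls call table (the output of [build_call_dataset], or any table
#'   with `user_id`, `call_start`, `vitality`, `valid`).
#' @param users user table with `user_id`, `sex`.
#' @param bdi BDI table with `user_id`, `administered_at`, `score`,
#'   `completion_time_s`, `ordinal`.
#' @param k,window_days,min_points mental-activity parameters.
#' @param ma_direction which mental-activity points may anchor to the BDI
#'   time: `"both"` (default; latest point within +-`window_days`, preferring
#'   points at or before the BDI time on ties), `"before"`, or `"after"`.
#' @return data.frame with one row per retained user: `user_id`, `sex`,
#'   `bdi_at`, `bdi_score`, `completion_time_s`, `bdi_category`, `vitality`,
#'   `vitality_at`, `mental_activity`, `mental_activity_at`.
#' @export
build_user_dataset <- function(calls, users, bdi, k = 1, window_days = 14,
                               min_points = 5,
                               ma_direction = c("both", "before", "after")) {
  ma_direction <- match.arg(ma_direction)
  calls$call_start <- as_utc(calls$call_start)
  bdi$administered_at <- as_utc(bdi$administered_at)
  first_bdi <- do.call(rbind, lapply(split(bdi, bdi$user_id, drop = TRUE),
    function(d) d[which.min(d$administered_at), , drop = FALSE]))
  valid_calls <- calls[calls$valid & !is.na(calls$vitality), , drop = FALSE]
  valid_calls <- valid_calls[order(valid_calls$user_id, valid_calls$call_start), ]

  rows <- lapply(seq_len(nrow(first_bdi)), function(i) {
    b <- first_bdi[i, ]
    uc <- valid_calls[valid_calls$user_id == b$user_id, , drop = FALSE]
    if (nrow(uc) == 0L) return(NULL)
    bt <- as.numeric(b$administered_at)
    after <- uc[as.numeric(uc$call_start) > bt, , drop = FALSE]
    if (nrow(after) == 0L) return(NULL)
    v_row <- after[1L, ]

    ma <- mental_activity_series(
      data.frame(time = uc$call_start, value = uc$vitality),
      k = k, window_days = window_days, min_points = min_points)
    if (nrow(ma) == 0L) return(NULL)
    mt <- as.numeric(ma$time)
    win <- window_days * DAY_S
    cand <- switch(ma_direction,
      both   = which(abs(mt - bt) <= win),
      before = which(mt <= bt & mt >= bt - win),
      after  = which(mt >= bt & mt <= bt + win))
    if (length(cand) == 0L) return(NULL)
    # latest point; when a pre-BDI and post-BDI point are equally late pick
    # the pre-BDI one (ties only arise in "both" mode)
    dist_late <- mt[cand]
    pick <- cand[order(-dist_late, mt[cand] > bt)][1L]
    data.frame(user_id = b$user_id,
               sex = users$sex[match(b$user_id, users$user_id)],
               bdi_at = b$administered_at, bdi_score = b$score,
               completion_time_s = b$completion_time_s,
               vitality = v_row$vitality, vitality_at = v_row$call_start,
               mental_activity = ma$value[pick],
               mental_activity_at = ma$time[pick])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(user_id = character(0), sex = character(0),
                      bdi_at = as_utc(numeric(0)), bdi_score = integer(0),
                      completion_time_s = numeric(0), vitality = numeric(0),
                      vitality_at = as_utc(numeric(0)),
                      mental_activity = numeric(0),
                      mental_activity_at = as_utc(numeric(0)))
  out$bdi_category <- if (nrow(out)) categorize_bdi(out$bdi_score) else
    factor(character(0), levels = c("normal", "abnormal"))
  rownames(out) <- NULL
  out
}

# --- CSV dialects ----------------------------------------------------------
# Column layouts are fixed so files round-trip bit-exactly:
#   calls: user_id, call_start, duration_s, vitality, valid, n_utterances
#   users: user_id, consent_at, sex, age, region, hist_depression,
#          present_depression
#   bdi:   user_id, administered_at, score, completion_time_s, ordinal

#' Read / write the monitoring CSV dialects
#'
#' Fixed-layout CSV readers and writers for the three longitudinal tables
#' (calls, users, BDI records). Timestamps are ISO-8601 UTC; numeric columns
#' are written with fixed precision so identical inputs produce byte-identical
#' files.
#'
#' @param x the table to write.
#' @param path file path.
#' @return readers return a data.frame with parsed timestamp columns; writers
#'   return `path` invisibly.
#' @name monitoring_csv
NULL

#' @rdname monitoring_csv
#' @export
write_calls_csv <- function(x, path) {
  out <- data.frame(user_id = x$user_id,
                    call_start = format_utc(x$call_start),
                    duration_s = sprintf("%.1f", x$duration_s),
                    vitality = ifelse(is.na(x$vitality), "",
                                      sprintf("%.6f", x$vitality)),
                    valid = ifelse(x$valid, "true", "false"),
                    n_utterances = x$n_utterances)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname monitoring_csv
#' @export
read_calls_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(user_id = "character"))
  x$call_start <- as_utc(x$call_start)
  x$vitality <- suppressWarnings(as.numeric(x$vitality))
  x$valid <- x$valid %in% c("true", "TRUE", "True")
  x
}

#' @rdname monitoring_csv
#' @export
write_users_csv <- function(x, path) {
  out <- data.frame(user_id = x$user_id,
                    consent_at = format_utc(x$consent_at),
                    sex = x$sex, age = x$age, region = x$region,
                    hist_depression = ifelse(x$hist_depression, "true", "false"),
                    present_depression = ifelse(x$present_depression, "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname monitoring_csv
#' @export
read_users_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(user_id = "character"))
  x$consent_at <- as_utc(x$consent_at)
  x$hist_depression <- x$hist_depression %in% c("true", "TRUE", "True")
  x$present_depression <- x$present_depression %in% c("true", "TRUE", "True")
  x
}

#' @rdname monitoring_csv
#' @export
write_bdi_csv <- function(x, path) {
  out <- data.frame(user_id = x$user_id,
                    administered_at = format_utc(x$administered_at),
                    score = x$score,
                    completion_time_s = sprintf("%.1f", x$completion_time_s),
                    ordinal = x$ordinal)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname monitoring_csv
#' @export
read_bdi_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(user_id = "character"))
  x$administered_at <- as_utc(x$administered_at)
  x
}
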