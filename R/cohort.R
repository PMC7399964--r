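#' Chi-square goodness of fit to a normal distribution, with effect size w
#'
#' Bins the sample into `n_bins` equal-probability bins under the normal
#' distribution fitted by the sample mean and standard deviation, and runs a
#' chi-square test of the observed counts against the equal expected counts.
#' The effect size is `w = sqrt(chi_square / n)`; by the usual convention
#' w < 0.1 is a small (negligible) departure, so large samples can reject
#' normality while the departure remains immaterial. Degrees of freedom are
#' `n_bins - 3` (two fitted parameters).
#'
#' @param x numeric sample, `length(x) >= 5 * n_bins`.
#' @param n_bins number of bins; default `max(5, min(20, floor(n/50)))`.
#' @return object of class `gof_normal`: list with `chi_square`, `p_value`,
#'   `effect_size_w`, `n_bins`, `n`, `mean`, `sd`, `observed`, `expected`.
#' @export
#' @examples
#' set.seed(1)
#' gof_normal(rnorm(2000, 0.56, 0.09))
gof_normal <- function(x, n_bins = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (is.null(n_bins)) n_bins <- max(5L, min(20L, floor(n / 50)))
  if (n_bins < 3L) stop("need at least 3 bins")
  if (n < 5L * n_bins)
    stop("need n >= 5 * n_bins (", 5L * n_bins, "), got ", n)
  m <- mean(x); s <- stats::sd(x)
  if (s <= 0) stop("sample is constant; normality test undefined")
  breaks <- stats::qnorm(seq(0, 1, length.out = n_bins + 1L), m, s)
  breaks[1] <- -Inf; breaks[n_bins + 1L] <- Inf
  observed <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                    left.open = TRUE), nbins = n_bins)
  expected <- rep(n / n_bins, n_bins)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- n_bins - 3L
  structure(list(chi_square = chi2,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 effect_size_w = sqrt(chi2 / n),
                 n_bins = n_bins, df = df, n = n, mean = m, sd = s,
                 observed = observed, expected = expected),
            class = "gof_normal")
}

#' @export
print.gof_normal <- function(x, ...) {
  cat("Chi-square goodness of fit to fitted normal\n")
  cat(sprintf("  n = %d, bins = %d, X-squared = %.3f, df = %d, p = %.3g\n",
              x$n, x$n_bins, x$chi_square, x$df, x$p_value))
  cat(sprintf("  effect size w = %.4f (%s departure)\n", x$effect_size_w,
              if (x$effect_size_w < 0.1) "negligible/small" else
                if (x$effect_size_w < 0.3) "small-medium" else "medium-large"))
  invisible(x)
}

#' @export
plot.gof_normal <- function(x, ...) {
  graphics::barplot(rbind(x$observed, x$expected), beside = TRUE,
                    names.arg = seq_len(x$n_bins), legend.text = c("observed", "expected"),
                    xlab = "equal-probability bin", ylab = "count", ...)
  invisible(x)
}

# pooled standard deviation from two groups' sample variances
pooled_sd <- function(sd_a, n_a, sd_b, n_b) {
  sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
}

#' Two-group mean comparison with Cohen's d
#'
#' Two-sided t test (Welch by default, Student optional) plus Cohen's d with
#' the pooled standard deviation. `compare_groups` takes raw samples;
#' `compare_groups_stats` takes exact summary statistics and gives identical
#' results for summaries computed from the same data.
#'
#' @param values_a,values_b numeric samples, each of length at least 2.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return object of class `group_comparison`: list with `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `n_a`, `n_b`, `t_statistic`, `df`, `p_value`,
#'   `cohens_d`.
#' @export
#' @examples
#' compare_groups_stats(0.56, 0.095, 423, 0.53, 0.085, 154)$cohens_d  # ~0.32
compare_groups <- function(values_a, values_b, var_equal = FALSE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  compare_groups_stats(mean(values_a), stats::sd(values_a), length(values_a),
                       mean(values_b), stats::sd(values_b), length(values_b),
                       var_equal = var_equal)
}

#' @rdname compare_groups
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics (sample
#'   means, sample standard deviations, sizes).
#' @export
compare_groups_stats <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 var_equal = FALSE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  sp <- pooled_sd(sd_a, n_a, sd_b, n_b)
  diff <- mean_a - mean_b
  if (sd_a == 0 && sd_b == 0) {
    # degenerate: no within-group variance
    t_stat <- if (diff == 0) 0 else Inf * sign(diff)
    df <- n_a + n_b - 2
    p <- if (diff == 0) 1 else 0
    d <- if (diff == 0) 0 else Inf
  } else if (var_equal) {
    se <- sp * sqrt(1 / n_a + 1 / n_b)
    t_stat <- diff / se
    df <- n_a + n_b - 2
    p <- 2 * stats::pt(-abs(t_stat), df)
    d <- abs(diff) / sp
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    t_stat <- diff / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
    d <- abs(diff) / sp
  }
  structure(list(mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
                 n_a = n_a, n_b = n_b, t_statistic = t_stat, df = df,
                 p_value = p, cohens_d = d,
                 method = if (var_equal) "student" else "welch"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison (%s t test)\n", x$method))
  cat(sprintf("  A: mean %.4f (SD %.4f, n %d)   B: mean %.4f (SD %.4f, n %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g, Cohen's d = %.3f\n",
              x$t_statistic, x$df, x$p_value, x$cohens_d))
  invisible(x)
}

#' Correlation between questionnaire scores and voice indices
#'
#' Pearson (default) or Spearman correlation with a two-sided p value; a thin
#' wrapper around [stats::cor.test] that flags constant input instead of
#' erroring.
#'
#' @param x,y paired numeric vectors, `n >= 3` after removing incomplete
#'   pairs.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p_value`, `n`, `method`, `defined` (FALSE with
#'   `r = NA` when either input is constant).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                method = method, defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method, defined = TRUE)
}

#' Pre/post event-window analysis by region
#'
#' For a dated life event (e.g. a major earthquake), compares each region's
#' voice indices across the 14-day windows either side of the event: mean
#' call vitality over `(event - window, event)` vs `[event, event + window)`,
#' and, per user, the most recent mental-activity value from before the event
#' vs the most recent within `[event, event + window)`, averaged per region.
#' Regions with no data in a window get NA, never zero.
#'
#' @param calls valid-call table with `user_id`, `call_start`, `vitality`.
#' @param ma_points mental-activity points with `user_id`, `time`, `value`
#'   (e.g. rbind of [mental_activity_series] per user).
#' @param users user table with `user_id`, `region`.
#' @param event_at event timestamp.
#' @param window_days window length in days (default 14).
#' @return data.frame of class `event_study`: one row per region with
#'   `region`, `pre_mean_vitality`, `post_mean_vitality`, `n_pre`, `n_post`,
#'   `pre_mental_activity`, `post_mental_activity`, `n_users_pre_ma`,
#'   `n_users_post_ma`.
#' @export
event_window_analysis <- function(calls, ma_points, users, event_at,
                                  window_days = 14) {
  ev <- as.numeric(as_utc(event_at))
  win <- window_days * DAY_S
  ct <- as.numeric(as_utc(calls$call_start))
  calls$region <- users$region[match(calls$user_id, users$user_id)]
  ma_points$region <- users$region[match(ma_points$user_id, users$user_id)]
  mt <- as.numeric(as_utc(ma_points$time))

  regions <- sort(unique(users$region))
  rows <- lapply(regions, function(rg) {
    rc <- calls$region %in% rg
    pre <- rc & ct > ev - win & ct < ev
    post <- rc & ct >= ev & ct < ev + win
    # per-user latest mental activity: any time pre-event; within the window
    # post-event
    rm_idx <- which(ma_points$region %in% rg)
    pre_ma <- post_ma <- numeric(0)
    if (length(rm_idx)) {
      d <- ma_points[rm_idx, , drop = FALSE]
      dt <- mt[rm_idx]
      pre_ma <- vapply(split(seq_along(dt), d$user_id), function(ii) {
        ii <- ii[dt[ii] < ev]
        if (length(ii)) d$value[ii[which.max(dt[ii])]] else NA_real_
      }, numeric(1))
      post_ma <- vapply(split(seq_along(dt), d$user_id), function(ii) {
        ii <- ii[dt[ii] >= ev & dt[ii] < ev + win]
        if (length(ii)) d$value[ii[which.max(dt[ii])]] else NA_real_
      }, numeric(1))
      pre_ma <- pre_ma[!is.na(pre_ma)]
      post_ma <- post_ma[!is.na(post_ma)]
    }
    if (!any(rc) && !length(rm_idx))
      message("event_window_analysis: no data for region ", rg)
    data.frame(region = rg,
               pre_mean_vitality = if (any(pre)) mean(calls$vitality[pre]) else NA_real_,
               post_mean_vitality = if (any(post)) mean(calls$vitality[post]) else NA_real_,
               n_pre = sum(pre), n_post = sum(post),
               pre_mental_activity = if (length(pre_ma)) mean(pre_ma) else NA_real_,
               post_mental_activity = if (length(post_ma)) mean(post_ma) else NA_real_,
               n_users_pre_ma = length(pre_ma),
               n_users_post_ma = length(post_ma))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_study", "data.frame")
  attr(out, "event_at") <- as_utc(event_at)
  attr(out, "window_days") <- window_days
  out
}

#' @export
plot.event_study <- function(x, ...) {
  m <- t(as.matrix(x[, c("pre_mean_vitality", "post_mean_vitality")]))
  graphics::barplot(m, beside = TRUE, names.arg = x$region,
                    legend.text = c("pre", "post"), ylab = "mean vitality",
                    main = sprintf("Vitality %d days either side of event",
                                   attr(x, "window_days")), ...)
  invisible(x)
}

#' Cohort demographic summary
#'
#' Counts and two-decimal half-up percentages for sex, depression history,
#' present depression and region, plus means/SDs for age, initial BDI score,
#' calls per user and inter-call interval in hours.
#'
#' @param users user table (`user_id`, `sex`, `age`, `region`,
#'   `hist_depression`, `present_depression`).
#' @param calls call table (`user_id`, `call_start`); may be the full or the
#'   filtered table.
#' @param bdi BDI table (`user_id`, `administered_at`, `score`); the earliest
#'   record per user is used.
#' @return object of class `cohort_summary`: list with `n_users`,
#'   `categorical` (data.frame: item, n, pct) and `continuous` (data.frame:
#'   item, mean, sd).
#' @export
summarize_cohort <- function(users, calls, bdi) {
  n <- nrow(users)
  if (n == 0L) stop("empty user table")
  cat_rows <- list(
    data.frame(item = "sex_men", n = sum(users$sex == "man"),
               pct = percent_of(sum(users$sex == "man"), n)),
    data.frame(item = "hist_depression", n = sum(users$hist_depression),
               pct = percent_of(sum(users$hist_depression), n)),
    data.frame(item = "present_depression", n = sum(users$present_depression),
               pct = percent_of(sum(users$present_depression), n)))
  for (rg in sort(unique(users$region))) {
    k <- sum(users$region == rg)
    cat_rows[[length(cat_rows) + 1L]] <-
      data.frame(item = paste0("region_", rg), n = k, pct = percent_of(k, n))
  }

  calls$call_start <- as_utc(calls$call_start)
  per_user_calls <- as.numeric(table(factor(calls$user_id, levels = users$user_id)))
  gaps_h <- unlist(lapply(split(as.numeric(calls$call_start), calls$user_id),
                          function(t) if (length(t) > 1) diff(sort(t)) / 3600 else numeric(0)),
                   use.names = FALSE)
  first_bdi <- vapply(split(bdi, bdi$user_id, drop = TRUE),
                      function(d) d$score[which.min(as_utc(d$administered_at))],
                      numeric(1))
  msd <- function(x) if (length(x)) c(mean(x), stats::sd(x)) else c(NA_real_, NA_real_)
  cont <- rbind(age = msd(users$age), bdi_initial = msd(first_bdi),
                calls_per_user = msd(per_user_calls),
                intercall_interval_h = msd(gaps_h))
  structure(list(n_users = n,
                 categorical = do.call(rbind, cat_rows),
                 continuous = data.frame(item = rownames(cont),
                                         mean = cont[, 1], sd = cont[, 2],
                                         row.names = NULL)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d users\n", x$n_users))
  cat("Categorical (n, %):\n")
  print(x$categorical, row.names = FALSE)
  cat("Continuous (mean, SD):\n")
  print(transform(x$continuous, mean = round(mean, 2), sd = round(sd, 2)),
        row.names = FALSE)
  invisible(x)
}
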