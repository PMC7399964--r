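#' Plan for synthetic call audio
#'
#' Describes a call as a list of planned utterances over a Gaussian noise
#' floor. Each utterance is a harmonic tone (fundamental plus two harmonics)
#' whose F0 moves linearly from `f0_start_hz` to `f0_end_hz`.
#'
#' @param plan data.frame with columns `start_s`, `duration_s`, `f0_start_hz`,
#'   `f0_end_hz`, `amplitude` (peak, in (0, 1\]); utterances must not overlap.
#' @param sample_rate sampling rate in Hz (default 8000, telephone band).
#' @param noise_floor peak scale of the background noise; must stay below the
#'   smallest utterance amplitude (default 0.005).
#' @return an object of class `audio_spec`.
#' @export
audio_spec <- function(plan, sample_rate = 8000, noise_floor = 0.005) {
  req <- c("start_s", "duration_s", "f0_start_hz", "f0_end_hz", "amplitude")
  if (!all(req %in% names(plan)))
    stop("plan must have columns ", paste(req, collapse = ", "))
  if (nrow(plan)) {
    plan <- plan[order(plan$start_s), , drop = FALSE]
    if (any(plan$duration_s <= 0)) stop("utterance durations must be > 0")
    if (any(plan$amplitude <= 0 | plan$amplitude > 1))
      stop("amplitudes must lie in (0, 1]")
    ends <- plan$start_s + plan$duration_s
    if (nrow(plan) > 1 && any(plan$start_s[-1] < ends[-nrow(plan)]))
      stop("planned utterances overlap")
    if (noise_floor >= min(plan$amplitude))
      stop("noise_floor must be below the smallest utterance amplitude")
  }
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  structure(list(plan = plan, sample_rate = sample_rate,
                 noise_floor = noise_floor),
            class = "audio_spec")
}

#' Generate speech-like call audio from a plan
#'
#' Renders each planned utterance as an amplitude-modulated harmonic tone
#' (fundamental plus two harmonics at relative amplitudes 1, 0.5, 0.25;
#' linear F0 interpolation; 5 ms raised-cosine edge ramps) over a Gaussian
#' noise floor. Fully deterministic for a given seed.
#'
#' @param spec an [audio_spec].
#' @param seed integer seed for the noise (mandatory).
#' @param tail_s trailing silence after the last utterance (default 0.5 s).
#' @return an [audio_signal].
#' @export
generate_call_audio <- function(spec, seed, tail_s = 0.5) {
  stopifnot(inherits(spec, "audio_spec"))
  check_scalar(seed, "seed")
  sr <- spec$sample_rate
  total_s <- if (nrow(spec$plan))
    max(spec$plan$start_s + spec$plan$duration_s) + tail_s else tail_s
  n <- ceiling(total_s * sr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  x <- stats::rnorm(n, 0, spec$noise_floor / 3)
  for (i in seq_len(nrow(spec$plan))) {
    u <- spec$plan[i, ]
    m <- round(u$duration_s * sr)
    t <- (seq_len(m) - 1) / sr
    f0 <- u$f0_start_hz + (u$f0_end_hz - u$f0_start_hz) * t / u$duration_s
    phase <- 2 * pi * cumsum(f0) / sr
    tone <- (sin(phase) + 0.5 * sin(2 * phase) + 0.25 * sin(3 * phase)) / 1.75
    # gentle 4 Hz syllabic amplitude modulation + 5 ms edge ramps
    am <- 1 - 0.1 * (0.5 + 0.5 * sin(2 * pi * 4 * t))
    ramp_n <- min(m %/% 2, round(0.005 * sr))
    if (ramp_n > 0) {
      r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      am[seq_len(ramp_n)] <- am[seq_len(ramp_n)] * r
      am[(m - ramp_n + 1):m] <- am[(m - ramp_n + 1):m] * rev(r)
    }
    idx <- round(u$start_s * sr) + seq_len(m)
    x[idx] <- x[idx] + u$amplitude * am * tone
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  audio_signal(pmin(1, pmax(-1, x)), sr)
}

#' Longitudinal cohort simulation parameters
#'
#' Generative model for a monitoring cohort: each user carries a latent
#' vitality trait drawn per sex; calls arrive as a Poisson process over the
#' user's active period (exponential dropout); each call's vitality is the
#' latent trait plus Gaussian noise, clipped to \[0, 1\]; configurable
#' fractions of calls fail the duration and utterance-count validity rules;
#' users in exposed regions have their trait stepped down by `event_delta` at
#' the event date with exponential recovery; BDI questionnaire scores depend
#' negatively on the latent trait.
#'
#' The per-sex `vitality_mean`/`vitality_sd` are the target *marginal*
#' distribution of valid call vitality; the between-user trait SD is derived
#' as `sqrt(vitality_sd^2 - call_noise_sd^2)` so generated samples converge
#' to the configured values.
#'
#' @param n_users number of users.
#' @param seed mandatory integer seed.
#' @param study_start study opening date (UTC).
#' @param study_days length of the collection window in days (default 730).
#' @param sex_ratio_men probability a user is a man (default 0.6257).
#' @param vitality_mean,vitality_sd named vectors (`man`, `woman`) of the
#'   marginal call-vitality mean/SD (defaults 0.57/0.095 men, 0.53/0.085
#'   women).
#' @param call_noise_sd within-user per-call vitality noise SD (default
#'   0.08); must be below both `vitality_sd` entries.
#' @param mean_call_interval_h mean inter-call interval in hours (default
#'   6.37, exponential gaps).
#' @param dropout_hazard_per_day daily hazard of stopping use (default 0.01).
#' @param p_short_call fraction of calls shorter than 10 s (default 0.05).
#' @param p_few_utterances fraction of calls with fewer than 6 utterances
#'   (default 0.10).
#' @param regions data.frame with `name`, `prob`, `exposed`; defaults mirror
#'   the national region mix with one exposed region (Kumamoto).
#' @param event_at event date (default 2016-04-14, nine months in).
#' @param event_delta latent-trait drop for exposed users at the event
#'   (default 0 = no event).
#' @param event_half_life_days exponential recovery half-life (default 180;
#'   `Inf` for a permanent step).
#' @param bdi_intercept,bdi_slope,bdi_noise_sd BDI model
#'   `score = round(clip(intercept - slope*latent + noise, 0, 63))`
#'   (defaults 29, 30, 10: population mean near 12, SD near 10, weak
#'   negative correlation with the trait).
#' @param completion_meanlog,completion_sdlog lognormal BDI completion-time
#'   parameters (defaults put ~10% below 80 s and ~10% above 300 s).
#' @param age_mean,age_sd adult age distribution, truncated at 18 (defaults
#'   39.97, 12.14).
#' @param p_hist_depression,p_present_depression prevalence of declared
#'   depression history / present illness (defaults 0.1246, 0.0761).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_users, seed,
                          study_start = "2015-07-20", study_days = 730,
                          sex_ratio_men = 0.6257,
                          vitality_mean = c(man = 0.57, woman = 0.53),
                          vitality_sd = c(man = 0.095, woman = 0.085),
                          call_noise_sd = 0.08,
                          mean_call_interval_h = 6.37,
                          dropout_hazard_per_day = 0.01,
                          p_short_call = 0.05, p_few_utterances = 0.10,
                          regions = NULL,
                          event_at = "2016-04-14", event_delta = 0,
                          event_half_life_days = 180,
                          bdi_intercept = 29, bdi_slope = 30, bdi_noise_sd = 10,
                          completion_meanlog = log(155), completion_sdlog = 0.516,
                          age_mean = 39.97, age_sd = 12.14,
                          p_hist_depression = 0.1246,
                          p_present_depression = 0.0761) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  check_scalar(seed, "seed")
  check_scalar(n_users, "n_users", positive = TRUE)
  if (is.null(regions))
    regions <- data.frame(
      name = c("Hokkaido", "Tohoku", "Kanto", "Chubu", "Kansai", "Chugoku",
               "Shikoku", "Kumamoto", "Kyushu", "Other"),
      prob = c(0.0276, 0.0491, 0.5397, 0.1174, 0.1125, 0.0391,
               0.0149, 0.0300, 0.0532, 0.0165),
      exposed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, TRUE, FALSE, FALSE))
  stopifnot(all(c("name", "prob", "exposed") %in% names(regions)),
            abs(sum(regions$prob) - 1) < 1e-6)
  for (p in c(sex_ratio_men, p_short_call, p_few_utterances,
              p_hist_depression, p_present_depression))
    check_unit(p, "probability")
  stopifnot(setequal(names(vitality_mean), c("man", "woman")),
            setequal(names(vitality_sd), c("man", "woman")),
            all(vitality_sd > 0), call_noise_sd > 0)
  if (any(call_noise_sd >= vitality_sd))
    stop("call_noise_sd must be below each per-sex vitality_sd ",
         "(the between-user trait SD is sqrt(vitality_sd^2 - call_noise_sd^2))")
  cfg <- list(n_users = as.integer(n_users), seed = as.integer(seed),
              study_start = as_utc(study_start), study_days = study_days,
              sex_ratio_men = sex_ratio_men,
              vitality_mean = vitality_mean, vitality_sd = vitality_sd,
              call_noise_sd = call_noise_sd,
              mean_call_interval_h = mean_call_interval_h,
              dropout_hazard_per_day = dropout_hazard_per_day,
              p_short_call = p_short_call, p_few_utterances = p_few_utterances,
              regions = regions, event_at = as_utc(event_at),
              event_delta = event_delta,
              event_half_life_days = event_half_life_days,
              bdi_intercept = bdi_intercept, bdi_slope = bdi_slope,
              bdi_noise_sd = bdi_noise_sd,
              completion_meanlog = completion_meanlog,
              completion_sdlog = completion_sdlog,
              age_mean = age_mean, age_sd = age_sd,
              p_hist_depression = p_hist_depression,
              p_present_depression = p_present_depression)
  class(cfg) <- "cohort_config"
  cfg
}

# latent trait at given times: baseline minus the (possibly recovering) event
# step for exposed users
latent_at <- function(base, exposed, t_num, cfg) {
  ev <- as.numeric(cfg$event_at)
  shock <- ifelse(exposed & t_num >= ev,
                  cfg$event_delta *
                    if (is.finite(cfg$event_half_life_days))
                      2^(-(t_num - ev) / (cfg$event_half_life_days * DAY_S))
                    else 1,
                  0)
  base - shock
}

#' Generate a longitudinal monitoring cohort
#'
#' Draws users, call records (with per-call vitality, duration and utterance
#' counts subject to the validity-rule failure fractions) and BDI records
#' from a [cohort_config]. All randomness flows from the config's seed, so a
#' given config always yields the identical cohort.
#'
#' @param cfg a [cohort_config].
#' @return an object of class `cohort`: list with data.frames `users`,
#'   `calls`, `bdi` (the three monitoring CSV dialects) and the `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  n <- cfg$n_users
  study_start <- as.numeric(cfg$study_start)
  study_end <- study_start + cfg$study_days * DAY_S

  user_id <- sprintf("u%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio_men, "man", "woman")
  age <- pmax(18, round(stats::rnorm(n, cfg$age_mean, cfg$age_sd)))
  region <- sample(cfg$regions$name, n, replace = TRUE, prob = cfg$regions$prob)
  exposed <- cfg$regions$exposed[match(region, cfg$regions$name)]
  consent <- study_start + stats::runif(n, 0, cfg$study_days - 1) * DAY_S
  hist_dep <- stats::runif(n) < cfg$p_hist_depression
  pres_dep <- stats::runif(n) < cfg$p_present_depression

  trait_sd <- sqrt(cfg$vitality_sd^2 - cfg$call_noise_sd^2)
  base <- stats::rnorm(n, cfg$vitality_mean[sex], trait_sd[sex])

  active_days <- if (cfg$dropout_hazard_per_day > 0)
    stats::rexp(n, cfg$dropout_hazard_per_day) else rep(Inf, n)
  obs_days <- pmin(active_days, (study_end - consent) / DAY_S)

  # calls: Poisson process over each user's active period
  lambda <- obs_days * 24 / cfg$mean_call_interval_h
  n_calls <- stats::rpois(n, lambda)
  u <- rep(seq_len(n), n_calls)
  t_call <- consent[u] + stats::runif(length(u)) * obs_days[u] * DAY_S
  o <- order(u, t_call)
  u <- u[o]; t_call <- t_call[o]

  short <- stats::runif(length(u)) < cfg$p_short_call
  duration <- ifelse(short, stats::runif(length(u), 2, 10),
                     10 + stats::rlnorm(length(u), log(120), 0.8))
  few <- stats::runif(length(u)) < cfg$p_few_utterances
  n_utt <- ifelse(few, sample(1:5, length(u), replace = TRUE),
                  6L + stats::rpois(length(u), 8))
  valid <- duration >= 10 & n_utt >= 6
  vit <- pmin(1, pmax(0, latent_at(base[u], exposed[u], t_call, cfg) +
                           stats::rnorm(length(u), 0, cfg$call_noise_sd)))
  vit[!valid] <- NA_real_

  calls <- data.frame(user_id = user_id[u], call_start = as_utc(t_call),
                      duration_s = duration, vitality = vit, valid = valid,
                      n_utterances = as.integer(n_utt))

  # BDI: ordinals 1-3 at ~3-month spacing from consent, while still observed
  bu <- rep(seq_len(n), each = 3L)
  ord <- rep(1:3, n)
  t_bdi <- consent[bu] + ((ord - 1L) * 90 + stats::runif(3L * n, 0, 2)) * DAY_S
  keep <- (t_bdi - consent[bu]) / DAY_S <= obs_days[bu] & t_bdi <= study_end
  bu <- bu[keep]; ord <- ord[keep]; t_bdi <- t_bdi[keep]
  score <- round(pmin(63, pmax(0, cfg$bdi_intercept -
    cfg$bdi_slope * latent_at(base[bu], exposed[bu], t_bdi, cfg) +
    stats::rnorm(length(bu), 0, cfg$bdi_noise_sd))))
  completion <- stats::rlnorm(length(bu), cfg$completion_meanlog,
                              cfg$completion_sdlog)
  bdi <- data.frame(user_id = user_id[bu], administered_at = as_utc(t_bdi),
                    score = as.integer(score), completion_time_s = completion,
                    ordinal = ord)

  users <- data.frame(user_id = user_id, consent_at = as_utc(consent),
                      sex = sex, age = age, region = region,
                      hist_depression = hist_dep, present_depression = pres_dep)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(users = users, calls = calls, bdi = bdi, config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d users, %d calls (%.1f%% valid), %d BDI records>\n",
              nrow(x$users), nrow(x$calls), 100 * mean(x$calls$valid),
              nrow(x$bdi)))
  invisible(x)
}

#' Write a cohort to the three monitoring CSV files
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calls = file.path(dir, "calls.csv"),
             users = file.path(dir, "users.csv"),
             bdi = file.path(dir, "bdi.csv"))
  write_calls_csv(cohort$calls, paths["calls"])
  write_users_csv(cohort$users, paths["users"])
  write_bdi_csv(cohort$bdi, paths["bdi"])
  invisible(paths)
}
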