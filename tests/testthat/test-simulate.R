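test_that("planned utterances and F0 survive the audio round trip", {
  plan <- data.frame(start_s = c(0.5, 2.2, 4.0, 5.8, 7.6, 9.4),
                     duration_s = c(1.2, 1.0, 1.4, 1.1, 0.9, 1.3),
                     f0_start_hz = c(180, 200, 150, 220, 190, 170),
                     f0_end_hz = c(220, 200, 250, 180, 190, 230),
                     amplitude = c(0.5, 0.4, 0.6, 0.5, 0.45, 0.55))
  sig <- generate_call_audio(audio_spec(plan), seed = 21)
  utts <- segment_utterances(sig)
  expect_equal(nrow(utts), 6)
  frame <- attr(utts, "frame_s")
  expect_true(all(abs(utts$start_s - plan$start_s) <= frame + 1e-9))
  expect_true(all(abs(utts$end_s - (plan$start_s + plan$duration_s)) <=
                    frame + 1e-9))

  # constant-F0 plan: tracker mean within +-2 Hz of the plan
  tr <- extract_f0(sig, utts[2, ])
  expect_lt(abs(mean(tr$f0_hz[tr$voiced]) - 200), 2)
})

test_that("an empty plan segments to nothing", {
  spec <- audio_spec(data.frame(start_s = numeric(0), duration_s = numeric(0),
                                f0_start_hz = numeric(0),
                                f0_end_hz = numeric(0), amplitude = numeric(0)))
  sig <- generate_call_audio(spec, seed = 3)
  expect_equal(nrow(segment_utterances(sig)), 0)
})

test_that("overlapping plans and bad amplitudes are rejected", {
  expect_error(audio_spec(data.frame(start_s = c(0, 0.5), duration_s = 1,
                                     f0_start_hz = 200, f0_end_hz = 200,
                                     amplitude = 0.5)), "overlap")
  expect_error(audio_spec(data.frame(start_s = 0, duration_s = 1,
                                     f0_start_hz = 200, f0_end_hz = 200,
                                     amplitude = 1.5)), "\\(0, 1\\]")
  expect_error(audio_spec(data.frame(start_s = 0, duration_s = 1,
                                     f0_start_hz = 200, f0_end_hz = 200,
                                     amplitude = 0.3), noise_floor = 0.4),
               "noise_floor")
})

test_that("the same seed reproduces a cohort byte for byte", {
  cfg <- cohort_config(n_users = 25, seed = 99, study_days = 60)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("calls.csv", "users.csv", "bdi.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # different seed -> different cohort
  d3 <- tempfile()
  write_cohort(generate_cohort(cohort_config(n_users = 25, seed = 100,
                                             study_days = 60)), d3)
  expect_false(identical(readLines(file.path(d1, "calls.csv")),
                         readLines(file.path(d3, "calls.csv"))))
})

test_that("per-sex vitality converges to the configured marginals", {
  cfg <- cohort_config(n_users = 3000, seed = 414, study_days = 12,
                       mean_call_interval_h = 12, dropout_hazard_per_day = 0)
  co <- generate_cohort(cfg)
  v <- co$calls$vitality[co$calls$valid]
  sex <- co$users$sex[match(co$calls$user_id[co$calls$valid],
                            co$users$user_id)]
  trait_sd <- sqrt(cfg$vitality_sd^2 - cfg$call_noise_sd^2)
  for (s in c("man", "woman")) {
    x <- v[sex == s]
    n <- length(x)
    m_users <- length(unique(co$calls$user_id[co$calls$valid][sex == s]))
    expect_gt(n, 10000)
    # cluster-aware SE of the mean: within-user noise + between-user traits
    se_mean <- sqrt(cfg$call_noise_sd^2 / n + trait_sd[s]^2 / m_users)
    expect_lt(abs(mean(x) - cfg$vitality_mean[s]), 3 * se_mean)
    # sd converges too; allow a clustering design effect of 2 on the iid SE
    se_sd <- cfg$vitality_sd[s] / sqrt(2 * n)
    expect_lt(abs(sd(x) - cfg$vitality_sd[s]), 6 * se_sd)
  }
})

test_that("validity-rule failure fractions match their configuration", {
  cfg <- cohort_config(n_users = 400, seed = 415, study_days = 20,
                       p_short_call = 0.08, p_few_utterances = 0.15)
  co <- generate_cohort(cfg)
  n <- nrow(co$calls)
  p_short <- mean(co$calls$duration_s < 10)
  p_few <- mean(co$calls$n_utterances < 6)
  expect_lt(abs(p_short - 0.08), 4 * sqrt(0.08 * 0.92 / n))
  expect_lt(abs(p_few - 0.15), 4 * sqrt(0.15 * 0.85 / n))
  expect_equal(co$calls$valid,
               co$calls$duration_s >= 10 & co$calls$n_utterances >= 6)
  expect_true(all(is.na(co$calls$vitality) == !co$calls$valid))
})

test_that("a zero-delta event leaves exposed and control regions alike", {
  set.seed(416)
  regions <- data.frame(name = c("A", "B"), prob = c(0.5, 0.5),
                        exposed = c(TRUE, FALSE))
  did <- replicate(25, {
    cfg <- cohort_config(n_users = 60, seed = sample.int(1e6, 1),
                         study_days = 42, regions = regions,
                         event_at = "2015-08-10", event_delta = 0,
                         dropout_hazard_per_day = 0)
    co <- generate_cohort(cfg)
    es <- event_window_analysis(
      co$calls[co$calls$valid, ],
      data.frame(user_id = character(0), time = as.POSIXct(character(0)),
                 value = numeric(0)),
      co$users, cfg$event_at)
    (es$post_mean_vitality[es$region == "A"] -
       es$pre_mean_vitality[es$region == "A"]) -
      (es$post_mean_vitality[es$region == "B"] -
         es$pre_mean_vitality[es$region == "B"])
  })
  expect_lt(abs(mean(did)), 3 * sd(did) / sqrt(length(did)))
})

test_that("BDI scores relate weakly and negatively to the latent trait", {
  co <- generate_cohort(cohort_config(n_users = 600, seed = 417,
                                      study_days = 30))
  first <- co$bdi[co$bdi$ordinal == 1, ]
  expect_true(all(first$score >= 0 & first$score <= 63))
  # per-user mean vitality proxies the latent trait
  mv <- tapply(co$calls$vitality[co$calls$valid],
               co$calls$user_id[co$calls$valid], mean)
  r <- correlate(first$score, unname(mv[first$user_id]))
  expect_lt(r$r, 0)
  expect_gt(r$r, -0.5)  # weak, not strong
})

test_that("WAV files round-trip through the PCM16 writer and reader", {
  sig <- generate_call_audio(audio_spec(data.frame(
    start_s = 0.2, duration_s = 0.8, f0_start_hz = 200, f0_end_hz = 240,
    amplitude = 0.5)), seed = 7)
  path <- tempfile(fileext = ".wav")
  write_wav(sig, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, sig$sample_rate)
  expect_equal(length(back$samples), length(sig$samples))
  expect_lt(max(abs(back$samples - sig$samples)), 2 / 32767)
})

test_that("stereo WAV input is downmixed by channel averaging", {
  sr <- 8000
  left <- 0.5 * sin(2 * pi * 200 * seq_len(sr) / sr)
  right <- 0.1 * sin(2 * pi * 200 * seq_len(sr) / sr)
  inter <- as.integer(round(32767 * as.vector(rbind(left, right))))
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 2L), con, 2, endian = "little")
  writeBin(sr, con, 4, endian = "little")
  writeBin(sr * 4L, con, 4, endian = "little")
  writeBin(c(4L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(inter) * 2L, con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  mono <- read_wav(path)
  expect_equal(length(mono$samples), sr)
  expect_lt(max(abs(mono$samples - (left + right) / 2)), 2 / 32767)
})
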