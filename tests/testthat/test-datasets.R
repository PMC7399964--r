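test_that("BDI categories split at 11", {
  expect_equal(as.character(categorize_bdi(c(0, 10, 11, 63))),
               c("normal", "normal", "abnormal", "abnormal"))
  expect_error(categorize_bdi(64), "\\[0, 63\\]")
  expect_error(categorize_bdi(-1), "\\[0, 63\\]")
})

test_that("completion-time band is inclusive at both ends", {
  bdi <- data.frame(user_id = letters[1:5],
                    completion_time_s = c(79, 80, 150, 300, 301))
  kept <- filter_by_completion_time(bdi)
  expect_equal(kept$user_id, c("b", "c", "d"))
  expect_equal(nrow(filter_by_completion_time(bdi[0, ])), 0)
})

test_that("percentile mode drops the top and bottom tails", {
  set.seed(407)
  bdi <- data.frame(user_id = sprintf("u%03d", 1:200),
                    completion_time_s = rlnorm(200, log(150), 0.6))
  kept <- filter_by_completion_time(bdi, mode = "percentile", trim = 0.10)
  q <- quantile(bdi$completion_time_s, c(0.10, 0.90), names = FALSE)
  expect_equal(nrow(kept), sum(bdi$completion_time_s >= q[1] &
                                 bdi$completion_time_s <= q[2]))
  expect_lt(nrow(kept), 200 * 0.85)  # the tails really came off
  expect_gt(nrow(kept), 200 * 0.75)
  expect_true(min(kept$completion_time_s) >
                quantile(bdi$completion_time_s, 0.09))
  expect_true(max(kept$completion_time_s) <
                quantile(bdi$completion_time_s, 0.91))
})

test_that("call dataset keeps users who attain mental activity, drops others", {
  users <- make_users(c("dense", "sparse"))
  dense <- make_calls("dense", seq(0, 3, length.out = 20), 0.6)
  sparse <- make_calls("sparse", c(0, 20, 40, 60), 0.6)
  cd <- build_call_dataset(rbind(dense, sparse), users)
  expect_equal(sort(unique(cd$user_id)), "dense")
  expect_equal(nrow(cd), 20)
  expect_true(all(cd$sex == "man"))
})

test_that("invalid calls and orphan users are filtered with a rejects report", {
  users <- make_users("u1")
  good <- make_calls("u1", 1:10, 0.5)
  bad_short <- make_calls("u1", 11, 0.5, duration_s = 5)
  bad_few <- make_calls("u1", 12, 0.5, n_utterances = 4)
  orphan <- make_calls("ghost", 1:6, 0.5)
  cd <- build_call_dataset(rbind(good, bad_short, bad_few, orphan), users)
  expect_equal(nrow(cd), 10)
  expect_equal(unique(cd$user_id), "u1")
  expect_equal(nrow(attr(cd, "rejects")), 6)
  expect_equal(unique(attr(cd, "rejects")$user_id), "ghost")
})

test_that("empty input gives empty output and the filter is idempotent", {
  users <- make_users("u1")
  empty <- make_calls("u1", numeric(0), numeric(0))
  expect_equal(nrow(build_call_dataset(empty, users)), 0)

  calls <- make_calls("u1", seq(0, 5, length.out = 12), runif(12, 0.4, 0.7))
  once <- build_call_dataset(calls, users)
  twice <- build_call_dataset(once, users)
  attr(once, "rejects") <- NULL
  attr(twice, "rejects") <- NULL
  expect_equal(twice, once)
})

test_that("stricter validity minima never add rows", {
  set.seed(408)
  users <- make_users(sprintf("u%02d", 1:8))
  calls <- do.call(rbind, lapply(users$user_id, function(id)
    make_calls(id, sort(runif(15, 0, 20)), runif(15, 0.3, 0.8),
               duration_s = sample(c(5, 30), 15, TRUE),
               n_utterances = sample(3:12, 15, TRUE))))
  sizes <- vapply(c(5, 7, 9), function(mp)
    nrow(build_call_dataset(calls, users, min_points = mp)), numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # raising the utterance minimum shrinks the valid set too
  revalid <- function(min_utt) {
    c2 <- calls
    c2$valid <- c2$duration_s >= 10 & c2$n_utterances >= min_utt
    c2$vitality[!c2$valid] <- NA
    nrow(build_call_dataset(c2, users))
  }
  expect_true(all(diff(vapply(c(6, 8, 10), revalid, numeric(1))) <= 0))
})

test_that("user dataset anchors to the initial BDI test", {
  users <- make_users("u1")
  # BDI at day 10; valid calls on days 11..20 -> day-11 vitality selected
  calls <- make_calls("u1", 11:20, seq(0.40, 0.58, by = 0.02))
  bdi <- data.frame(user_id = "u1",
                    administered_at = calls$call_start[1] - 86400,
                    score = 8, completion_time_s = 120, ordinal = 1)
  ud <- build_user_dataset(calls, users, bdi)
  expect_equal(nrow(ud), 1)
  expect_equal(ud$vitality, 0.40)
  expect_equal(as.character(ud$bdi_category), "normal")
  # the selected mental-activity point lies within 14 days of the BDI time
  expect_lte(abs(as.numeric(ud$mental_activity_at) -
                 as.numeric(ud$bdi_at)), 14 * 86400)
})

test_that("users without a post-BDI call or a nearby mental activity drop out", {
  users <- make_users(c("nocall", "latema"))
  # nocall: all calls before the BDI test
  calls_a <- make_calls("nocall", 1:10, 0.5)
  bdi_a <- data.frame(user_id = "nocall",
                      administered_at = calls_a$call_start[10] + 86400,
                      score = 5, completion_time_s = 100, ordinal = 1)
  # latema: mental activity only attainable ~20 days after the BDI test
  calls_b <- make_calls("latema", 20:29, 0.5)
  bdi_b <- data.frame(user_id = "latema",
                      administered_at = calls_b$call_start[1] - 20 * 86400,
                      score = 5, completion_time_s = 100, ordinal = 1)
  ud <- build_user_dataset(rbind(calls_a, calls_b), users,
                           rbind(bdi_a, bdi_b))
  expect_equal(nrow(ud), 0)
  # but latema qualifies when the anchoring window is wide enough to reach it
  ud2 <- build_user_dataset(calls_b, users[2, ], bdi_b, window_days = 30)
  expect_equal(nrow(ud2), 1)
})

test_that("the earliest BDI record is the anchor when several exist", {
  users <- make_users("u1")
  calls <- make_calls("u1", 5:20, 0.5)
  bdi <- data.frame(user_id = "u1",
                    administered_at = calls$call_start[c(10, 2)] + 3600,
                    score = c(20, 5), completion_time_s = 100,
                    ordinal = c(2, 1))
  ud <- build_user_dataset(calls, users, bdi)
  expect_equal(ud$bdi_score, 5)
  expect_equal(as.character(ud$bdi_category), "normal")
})

test_that("the CSV dialects round-trip", {
  co <- generate_cohort(cohort_config(n_users = 12, seed = 5, study_days = 60))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  calls <- read_calls_csv(paths[["calls"]])
  users <- read_users_csv(paths[["users"]])
  bdi <- read_bdi_csv(paths[["bdi"]])
  expect_equal(nrow(calls), nrow(co$calls))
  expect_equal(calls$valid, co$calls$valid)
  expect_equal(calls$vitality, co$calls$vitality, tolerance = 1e-6)
  expect_equal(as.numeric(calls$call_start), round(as.numeric(co$calls$call_start)))
  expect_equal(users$sex, co$users$sex)
  expect_equal(users$hist_depression, co$users$hist_depression)
  expect_equal(bdi$score, co$bdi$score)
})
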