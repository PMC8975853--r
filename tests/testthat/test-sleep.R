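ts <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

test_that("hourly_presence marks exactly the hours holding events", {
  day_start <- ts("2014-01-06T12:00:00")
  two_in_one_hour <- day_start + c(10, 40) * 60 # 12:10 and 12:40
  expect_identical(hourly_presence(two_in_one_hour, day_start),
                   c(1L, rep(0L, 23)))
  expect_identical(hourly_presence(ts(character(0)), day_start), rep(0L, 24))
  hourly <- day_start + 3600 * (0:23) + 60
  expect_identical(hourly_presence(hourly, day_start), rep(1L, 24))
})

test_that("detect_sleep finds the longest inactivity run in a noon window", {
  # activity clock hours 12-23 and 8-11, inactivity 0-7
  presence <- c(rep(1L, 12), rep(0L, 8), rep(1L, 4))
  rec <- detect_sleep(presence, anchor = 12)
  expect_identical(rec$sleep_hour, 0)
  expect_identical(rec$wake_hour, 8)
  expect_identical(rec$duration_hours, 8L)
  expect_identical(rec$mid_sleep_hour, 4)
})

test_that("equal-length runs resolve to the earliest run", {
  # midnight-anchored window: hours 1-4 and 14-17 inactive
  presence <- rep(1L, 24)
  presence[c(2:5, 15:18)] <- 0L
  rec <- detect_sleep(presence, anchor = 0)
  expect_identical(rec$sleep_hour, 1)
  expect_identical(rec$wake_hour, 5)
  expect_identical(rec$duration_hours, 4L)
})

test_that("windows without a usable episode return NULL", {
  expect_null(detect_sleep(rep(1L, 24)))
  expect_null(detect_sleep(rep(0L, 24)))
  # longest run touches the window end: wake-up never observed
  expect_null(detect_sleep(c(rep(1L, 10), rep(0L, 14))))
})

test_that("mid-sleep lies on the shorter arc between sleep and wake", {
  presence <- c(rep(1L, 9), rep(0L, 10), rep(1L, 5)) # sleep 21, wake 7
  rec <- detect_sleep(presence, anchor = 12)
  expect_identical(rec$sleep_hour, 21)
  expect_identical(rec$wake_hour, 7)
  expect_identical(rec$mid_sleep_hour, 2)
  d_sleep <- min(abs(rec$mid_sleep_hour - rec$sleep_hour),
                 24 - abs(rec$mid_sleep_hour - rec$sleep_hour))
  d_wake <- min(abs(rec$mid_sleep_hour - rec$wake_hour),
                24 - abs(rec$mid_sleep_hour - rec$wake_hour))
  expect_lte(d_sleep + d_wake, 12)
})

test_that("mode_hour applies the circular tie rules", {
  expect_identical(mode_hour(c(23, 23, 0, 1)), 23)
  # tie at {22, 2}: circular mean 0, both 2 h away -> earlier in
  # noon-anchored order wins, i.e. 22
  expect_identical(mode_hour(c(22, 22, 2, 2)), 22)
  expect_error(mode_hour(numeric(0)), "zero records")
})

test_that("summarize_sleep returns modes and the mean duration", {
  records <- data.frame(
    sleep_hour = c(23, 23, 0, 1),
    wake_hour = c(7, 8, 8, 8),
    mid_sleep_hour = c(3, 3.5, 4, 4.5),
    duration_hours = c(7, 8, 9, 8)
  )
  s <- summarize_sleep(records)
  expect_identical(s$typical_sleep, 23)
  expect_identical(s$typical_wake, 8)
  expect_identical(s$mean_duration, 8)
})

test_that("noise-free planted sleep windows are recovered exactly", {
  cfg <- generator_config(n_participants = 12, n_weeks = 4,
                          sleep_noise = "none", seed = 77)
  pop <- generate_population(cfg)
  recs <- infer_sleep(pop$log)
  n_windows <- 7L * 4L - 1L
  # every person-day yields a record, and it matches the planted hours
  expect_identical(nrow(recs), 12L * n_windows)
  truth_sleep <- pop$truth$typical_sleep[recs$user]
  truth_wake <- pop$truth$typical_wake[recs$user]
  expect_true(all(recs$sleep_hour == truth_sleep))
  expect_true(all(recs$wake_hour == truth_wake))
  expect_true(all(recs$duration_hours == pop$truth$typical_duration[recs$user]))
  # summaries then reproduce the planted typical times exactly
  s <- summarize_sleep_all(recs)
  expect_identical(s$typical_sleep, unname(pop$truth$typical_sleep[s$user]))
  expect_identical(s$typical_wake, unname(pop$truth$typical_wake[s$user]))
  expect_equal(s$typical_mid_sleep,
               unname(pop$truth$typical_mid_sleep[s$user]))
})

test_that("durations stay in [1, 24] on noisy synthetic data", {
  pop <- tiny_population()
  recs <- infer_sleep(pop$log)
  expect_true(all(recs$duration_hours >= 1 & recs$duration_hours <= 24))
  expect_true(all(recs$sleep_hour %in% 0:23))
  expect_true(all(recs$wake_hour %in% 0:23))
})

test_that("an always-on participant produces no sleep records", {
  log <- degenerate_cases("always_on")
  expect_error(suppressMessages(infer_sleep(log)), "no sleep episodes")
})
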