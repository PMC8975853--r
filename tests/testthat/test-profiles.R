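ts <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

week1 <- analysis_window(2014, 2, 2)

make_log <- function(users, hours_list, window = week1,
                     events = "screen_on") {
  t0 <- ts(paste0(format(window[1]), "T00:00:00"))
  dt <- data.table::rbindlist(Map(function(u, h) {
    data.table::data.table(user = u, event = events,
                           timestamp = t0 + h * 3600 + 600)
  }, users, hours_list))
  event_log(dt, window)
}

test_that("build_weekly_profile places mass by hand-computed fractions", {
  mon10 <- ts("2014-01-06T10:15:00")
  p <- build_weekly_profile(mon10)
  expect_identical(which(p$fractions > 0), 11L) # bin 10, one-based index 11
  expect_identical(p$fractions[11], 1)

  uniform <- ts("2014-01-06T00:30:00") + 3600 * (0:167)
  p <- build_weekly_profile(uniform)
  expect_equal(p$fractions, rep(1 / 168, 168))

  # 3 events Monday 09:xx, 1 event Friday 22:xx -> bins 9 and 4*24+22 = 118
  mixed <- c(ts("2014-01-06T09:05:00"), ts("2014-01-06T09:20:00"),
             ts("2014-01-06T09:50:00"), ts("2014-01-10T22:10:00"))
  p <- build_weekly_profile(mixed)
  expect_equal(p$fractions[10], 0.75)
  expect_equal(p$fractions[119], 0.25)
  expect_equal(sum(p$fractions), 1)

  expect_error(build_weekly_profile(ts(character(0))), "zero screen-on")
})

test_that("assemble_matrix validates shape and ids", {
  pr <- list(a = build_weekly_profile(ts("2014-01-06T10:15:00")),
             b = build_weekly_profile(ts("2014-01-07T20:15:00")))
  X <- assemble_matrix(pr)
  expect_identical(dim(X), c(2L, 168L))
  expect_identical(rownames(X), c("a", "b"))
  expect_identical(colnames(X)[c(1, 168)], c("h000", "h167"))

  expect_error(assemble_matrix(list(a = rep(1 / 24, 24))), "length 24")
  expect_error(assemble_matrix(list(pr[[1]], pr[[2]]),
                               ids = c("a", "a")), "duplicate")
})

test_that("profile rows are non-negative and sum to one after assembly", {
  pop <- tiny_population()
  X <- assemble_matrix(weekly_profiles(pop$log))
  expect_true(all(X >= 0))
  expect_true(all(abs(rowSums(X) - 1) < 1e-9))
  expect_identical(ncol(X), 168L)
})

test_that("population_average is the column mean and keeps unit mass", {
  X <- rbind(a = c(1, rep(0, 167)), b = c(0, 1, rep(0, 166)))
  avg <- population_average(X)
  expect_equal(unname(avg[1:2]), c(0.5, 0.5))
  expect_equal(sum(avg), 1)

  same <- rbind(a = rep(1 / 168, 168), b = rep(1 / 168, 168))
  expect_equal(population_average(same), rep(1 / 168, 168),
               ignore_attr = TRUE)
})

test_that("population average dips during the planted night hours", {
  pop <- tiny_population()
  X <- assemble_matrix(weekly_profiles(pop$log))
  avg <- rowMeans(matrix(population_average(X), nrow = 24))
  night_core <- mean(avg[c(4, 5, 6)]) # 03:00-05:00, asleep for everyone
  day <- mean(avg[9:24])
  expect_lt(night_core, day / 10)
})

test_that("filter_participants applies both inclusion criteria", {
  window <- analysis_window(2014, 2, 11) # 70 days, 10 weeks
  t0 <- ts(paste0(format(window[1]), "T00:00:00"))
  day_hours <- function(days) rep((days - 1) * 24 + 12, each = 5) + 0:4
  logs <- make_log(
    c("keeps", "few_days", "few_events"),
    list(day_hours(1:70),        # 70/70 days, 35 on-events/week
         day_hours(1:40),        # 40/70 days = 0.57
         (1:70 - 1) * 24 + 12),  # 70/70 days but 7 events/week
    window = window)
  kept <- filter_participants(logs, min_day_fraction = 0.8,
                              min_weekly_events = 20)
  expect_identical(sort(unique(kept$user)), "keeps")

  expect_error(filter_participants(degenerate_cases("empty")), "empty")
  expect_warning(filter_participants(logs, min_weekly_events = 1e6),
                 "all participants removed")
})

test_that("loosening either filter threshold never drops a participant", {
  pop <- generate_population(generator_config(
    n_participants = 8, n_weeks = 6, events_per_week_mean = 60,
    n_low_activity = 3, n_sparse_days = 3, seed = 99))
  kept_strict <- unique(filter_participants(pop$log, 0.8, 100)$user)
  for (args in list(c(0.5, 100), c(0.8, 40), c(0.5, 40))) {
    kept_loose <- unique(filter_participants(pop$log, args[1], args[2])$user)
    expect_true(all(kept_strict %in% kept_loose))
  }
})

test_that("profile matrix CSV round-trips", {
  pop <- tiny_population()
  X <- assemble_matrix(weekly_profiles(pop$log))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_matrix(X, path)
  back <- read_profile_matrix(path)
  expect_equal(back, X, tolerance = 1e-12)
})
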