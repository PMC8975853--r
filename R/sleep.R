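# Sleep inference by the longest-inactivity rule: within each noon-to-noon
# 24-hour window, hours with no screen-on event are "inactive"; the longest
# run of inactive hours is taken as the night's sleep episode. Noon-anchored
# windows keep a typical night's sleep contiguous, which midnight-anchored
# windows would bisect.

#' Hourly presence vector for one 24-hour window
#'
#' @param events POSIXct vector of one participant's screen-on timestamps.
#' @param day_start POSIXct start of the 24-hour window.
#' @return integer 0/1 vector of length 24; entry `h` is 1 iff at least one
#'   event falls in hour `h` of the window.
#' @export
hourly_presence <- function(events, day_start) {
  offs <- floor(as.numeric(difftime(events, day_start, units = "hours")))
  offs <- offs[offs >= 0 & offs < 24]
  v <- integer(24L)
  v[unique(offs) + 1L] <- 1L
  v
}

#' Detect the sleep episode in one 24-hour presence vector
#'
#' Finds the longest maximal run of zeros (earliest run wins ties). The
#' sleep hour is the clock hour of the run's first inactive hour, the wake
#' hour the clock hour of the first active hour after the run, the duration
#' the run length, and the mid-sleep time the circular midpoint of sleep and
#' wake hours. Returns `NULL` when no episode is defined: all hours active,
#' no hours active, or the longest run touching the end of the window (no
#' wake-up observed).
#'
#' @param presence 0/1 vector of length 24 from [hourly_presence()].
#' @param anchor clock hour at which the window starts (default 12, noon).
#' @return list with `sleep_hour`, `wake_hour`, `mid_sleep_hour`,
#'   `duration_hours`, or `NULL`.
#' @export
detect_sleep <- function(presence, anchor = 12L) {
  stopifnot(length(presence) == 24L)
  if (all(presence == 1L) || all(presence == 0L)) return(NULL)
  r <- rle(as.integer(presence))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zero <- which(r$values == 0L)
  len <- r$lengths[zero]
  pick <- zero[which.max(len)] # which.max takes the earliest among ties
  run_start <- starts[pick]
  run_end <- ends[pick]
  if (run_end == 24L) return(NULL) # no activity after the run: wake unseen
  sleep_hour <- (anchor + run_start - 1L) %% 24L
  wake_hour <- (anchor + run_end) %% 24L
  duration <- r$lengths[pick]
  list(sleep_hour = sleep_hour,
       wake_hour = wake_hour,
       mid_sleep_hour = circular_midpoint(sleep_hour, wake_hour),
       duration_hours = duration)
}

#' Per-day sleep records for every participant in a log
#'
#' Splits the observation window into consecutive 24-hour windows starting
#' at `anchor` o'clock of each day (the last, incomplete window is skipped),
#' computes the hourly presence of screen-on events, and applies
#' [detect_sleep()] to each window. Participants with a defined episode on
#' fewer than half their windows are reported in a message.
#'
#' @param log an [event_log()].
#' @param anchor clock hour anchoring the 24-hour windows (default 12).
#' @return data.table with columns `user`, `day`, `sleep_hour`, `wake_hour`,
#'   `mid_sleep_hour`, `duration_hours`; days without a defined episode are
#'   absent.
#' @export
infer_sleep <- function(log, anchor = 12L) {
  window <- log_window(log)
  n_days <- as.integer(window[2] - window[1]) + 1L
  n_windows <- n_days - 1L
  t0 <- as.POSIXct(paste0(format(window[1]), "T00:00:00"),
                   format = TS_FORMAT, tz = "UTC")
  dt <- data.table::as.data.table(log)[event == "screen_on"]
  if (nrow(dt) == 0L) stop("log contains no screen-on events")
  dt[, "hidx" := as.integer(floor(as.numeric(difftime(timestamp, t0, units = "hours"))))]
  by_user <- split(dt$hidx, dt$user)
  # hour indices of window j: anchor + 24 j + (0 .. 23)
  win_idx <- outer(seq_len(24L) - 1L, anchor + 24L * (seq_len(n_windows) - 1L), "+")
  out <- vector("list", length(by_user))
  low_coverage <- character(0)
  for (u in seq_along(by_user)) {
    present <- logical(n_days * 24L)
    hid <- by_user[[u]]
    hid <- hid[hid >= 0L & hid < n_days * 24L]
    present[hid + 1L] <- TRUE
    P <- matrix(present[win_idx + 1L], nrow = 24L)
    res <- vapply(seq_len(n_windows), function(j) {
      r <- detect_sleep(as.integer(P[, j]), anchor = anchor)
      if (is.null(r)) rep(NA_real_, 4L)
      else c(r$sleep_hour, r$wake_hour, r$mid_sleep_hour, r$duration_hours)
    }, numeric(4))
    ok <- which(!is.na(res[1L, ]))
    if (length(ok) < n_windows / 2) {
      low_coverage <- c(low_coverage, names(by_user)[u])
    }
    if (length(ok)) {
      out[[u]] <- data.table::data.table(
        user = names(by_user)[u], day = ok - 1L,
        sleep_hour = res[1L, ok], wake_hour = res[2L, ok],
        mid_sleep_hour = res[3L, ok], duration_hours = as.integer(res[4L, ok]))
    }
  }
  if (length(low_coverage)) {
    message("infer_sleep: sleep episode undefined on >50% of days for: ",
            paste(low_coverage, collapse = ", "))
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) stop("no sleep episodes detected for any participant")
  data.table::setcolorder(res, c("user", "day", "sleep_hour", "wake_hour",
                                 "mid_sleep_hour", "duration_hours"))
  res[]
}

#' Modal clock hour under noon-anchored ordering
#'
#' Returns the most frequent value; ties are broken toward the value closest
#' to the circular mean of all records, then toward the earliest value in
#' noon-anchored order (12, 13, ..., 23, 0, ..., 11).
#'
#' @param hours numeric vector of clock hours (integers or halves).
#' @return the modal clock hour.
#' @export
mode_hour <- function(hours) {
  if (length(hours) == 0L) stop("cannot take the mode of zero records")
  tab <- table(hours)
  cands <- as.numeric(names(tab)[tab == max(tab)])
  if (length(cands) == 1L) return(cands)
  cm <- circular_mean_hours(hours)
  d <- circular_dist_hours(cands, cm)
  cands <- cands[d == min(d)]
  cands[which.min(noon_anchor(cands))]
}

#' Summarize one participant's sleep records
#'
#' Typical sleep, wake and mid-sleep times are the modes of the per-day
#' distributions ([mode_hour()]); the typical duration is the arithmetic
#' mean of the per-day durations.
#'
#' @param records data.frame of one participant's sleep records (columns
#'   `sleep_hour`, `wake_hour`, `mid_sleep_hour`, `duration_hours`).
#' @return list with `typical_sleep`, `typical_wake`, `typical_mid_sleep`,
#'   `mean_duration`.
#' @export
summarize_sleep <- function(records) {
  if (nrow(records) == 0L) stop("no sleep records to summarize")
  list(typical_sleep = mode_hour(records$sleep_hour),
       typical_wake = mode_hour(records$wake_hour),
       typical_mid_sleep = mode_hour(records$mid_sleep_hour),
       mean_duration = mean(records$duration_hours))
}

#' Per-participant sleep summaries
#'
#' @param records output of [infer_sleep()] (all participants).
#' @return data.table with columns `user`, `typical_sleep`, `typical_wake`,
#'   `typical_mid_sleep`, `mean_duration`.
#' @export
summarize_sleep_all <- function(records) {
  records <- data.table::as.data.table(records)
  records[, {
    s <- summarize_sleep(.SD)
    data.table::as.data.table(s)
  }, by = "user"]
}
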