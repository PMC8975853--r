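# Reading, validating and writing screen-event logs, plus the calendar
# arithmetic (ISO weeks, hour-of-week bins) used by every downstream stage.
#
# All timestamps are treated as local wall-clock time. Parsing uses a fixed
# UTC representation internally so that no daylight-saving adjustment is ever
# applied: on DST transition days the 23- or 25-hour wall-clock day is binned
# by wall-clock hour with no correction.

EVENT_TYPES <- c("screen_on", "screen_off")
TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

#' Construct an event log object
#'
#' An `event_log` is a [data.table::data.table] with columns `user`
#' (character), `event` (`"screen_on"` / `"screen_off"`) and `timestamp`
#' (POSIXct, wall-clock), sorted by `(user, timestamp)`, carrying the closed
#' observation window as an attribute.
#'
#' @param records data.frame-like with columns `user`, `event`, `timestamp`.
#' @param window length-2 `Date` vector, the closed observation window.
#' @return an `event_log`.
#' @export
event_log <- function(records, window) {
  dt <- data.table::as.data.table(records)
  need <- c("user", "event", "timestamp")
  if (!all(need %in% names(dt))) {
    stop("event log needs columns: ", paste(need, collapse = ", "))
  }
  window <- as.Date(window)
  if (length(window) != 2L || any(is.na(window)) || window[1] > window[2]) {
    stop("window must be two ordered dates")
  }
  bad <- !dt$event %in% EVENT_TYPES
  if (any(bad)) {
    stop("unknown event type(s): ", paste(unique(dt$event[bad]), collapse = ", "))
  }
  if (!inherits(dt$timestamp, "POSIXct")) {
    dt[, "timestamp" := as.POSIXct(timestamp, format = TS_FORMAT, tz = "UTC")]
  }
  if (anyNA(dt$timestamp)) stop("unparseable timestamps in event records")
  if (nrow(dt)) {
    dates <- as.Date(dt$timestamp, tz = "UTC")
    if (any(dates < window[1] | dates > window[2])) {
      stop("record timestamps fall outside the observation window")
    }
  }
  data.table::setorderv(dt, c("user", "timestamp"))
  data.table::setattr(dt, "window", window)
  data.table::setattr(dt, "class", c("event_log", class(dt)))
  dt
}

#' @export
print.event_log <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<event_log> %d events, %d participants, window %s .. %s\n",
              nrow(x), data.table::uniqueN(x$user),
              format(w[1]), format(w[2])))
  if (nrow(x)) print(utils::head(data.table::as.data.table(x), 5))
  invisible(x)
}

#' Observation window of an event log
#' @param log an `event_log`.
#' @return length-2 `Date` vector.
#' @export
log_window <- function(log) attr(log, "window")

#' Date range covered by a range of ISO-8601 weeks
#'
#' @param year calendar year.
#' @param first_week,last_week ISO week numbers, `first_week <= last_week`.
#' @return length-2 `Date` vector: the Monday of `first_week` and the Sunday
#'   of `last_week`.
#' @export
analysis_window <- function(year, first_week, last_week) {
  nw <- iso_weeks_in_year(year)
  if (first_week < 1 || last_week > nw) {
    stop(sprintf("week numbers must lie in [1, %d] for %d", nw, year))
  }
  if (first_week > last_week) stop("first_week must not exceed last_week")
  # ISO week 1 is the week containing January 4th.
  jan4 <- as.Date(sprintf("%d-01-04", year))
  week1_monday <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  c(week1_monday + 7L * (first_week - 1L), week1_monday + 7L * last_week - 1L)
}

iso_weeks_in_year <- function(year) {
  as.integer(format(as.Date(sprintf("%d-12-28", year)), "%V"))
}

#' Number of days spanned by a range of ISO weeks
#'
#' @inheritParams analysis_window
#' @return `7 * (last_week - first_week + 1)`.
#' @examples
#' days_in_week_range(2014, 2, 51) # 350
#' @export
days_in_week_range <- function(year, first_week, last_week) {
  analysis_window(year, first_week, last_week) # validates the range
  7L * (as.integer(last_week) - as.integer(first_week) + 1L)
}

#' Hour-of-week index of a timestamp
#'
#' Bins run from Monday 00:00 (bin 0) to Sunday 23:00 (bin 167); sub-hour
#' times are floored to the containing hour.
#'
#' @param timestamp POSIXct vector (wall-clock).
#' @return integer vector in `[0, 167]`.
#' @export
hour_of_week <- function(timestamp) {
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, format = TS_FORMAT, tz = "UTC")
  }
  if (anyNA(timestamp)) stop("invalid timestamp")
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  dow <- (lt$wday + 6L) %% 7L # Monday = 0 ... Sunday = 6
  24L * dow + lt$hour
}

#' Read a screen-event log from CSV
#'
#' The dialect is a UTF-8 comma-separated file with header
#' `user,event,timestamp`, `event` one of `screen_on`/`screen_off`, and
#' `timestamp` in ISO-8601 `YYYY-MM-DDTHH:MM:SS`. Rows whose date falls
#' outside `window` are dropped (and counted in a message); malformed rows
#' raise an error naming the offending data row.
#'
#' @param path path to the CSV file.
#' @param window length-2 `Date` vector (see [analysis_window()]).
#' @return an [event_log()].
#' @export
read_event_log <- function(path, window) {
  if (!file.exists(path)) stop("event log file not found: ", path)
  dt <- data.table::fread(path, sep = ",", colClasses = "character",
                          header = TRUE, encoding = "UTF-8")
  if (!identical(names(dt), c("user", "event", "timestamp"))) {
    stop("event log header must be exactly 'user,event,timestamp', got: ",
         paste(names(dt), collapse = ","))
  }
  bad_event <- which(!dt$event %in% EVENT_TYPES)
  if (length(bad_event)) {
    stop(sprintf("unknown event token '%s' at data row %d",
                 dt$event[bad_event[1]], bad_event[1]))
  }
  ts <- as.POSIXct(dt$timestamp, format = TS_FORMAT, tz = "UTC")
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    stop(sprintf("unparseable timestamp '%s' at data row %d",
                 dt$timestamp[bad_ts[1]], bad_ts[1]))
  }
  dt[, "timestamp" := ts]
  window <- as.Date(window)
  dates <- as.Date(ts, tz = "UTC")
  keep <- dates >= window[1] & dates <= window[2]
  if (any(!keep)) {
    message(sprintf("read_event_log: dropped %d row(s) outside window %s .. %s",
                    sum(!keep), format(window[1]), format(window[2])))
  }
  event_log(dt[keep], window)
}

#' Write a screen-event log to CSV
#'
#' Inverse of [read_event_log()]: writing and re-reading yields an identical
#' log.
#'
#' @param log an `event_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  out <- data.table::data.table(
    user = log$user,
    event = log$event,
    timestamp = format(log$timestamp, TS_FORMAT, tz = "UTC")
  )
  data.table::fwrite(out, path)
  invisible(path)
}
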