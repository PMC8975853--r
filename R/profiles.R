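# Participant-inclusion filters and normalized 168-bin weekly activity
# profiles: the rows of the population matrix X that is factorized downstream.

N_BINS <- 168L

#' Apply the participant-inclusion filters
#'
#' A participant is retained when (a) they have at least one screen-on event
#' on at least `min_day_fraction` of the window's calendar days, and (b)
#' their combined screen-on + screen-off event count, averaged per week over
#' the window, is at least `min_weekly_events`.
#'
#' @param log an [event_log()] restricted to the analysis window.
#' @param min_day_fraction minimum fraction of active days (default 0.80).
#' @param min_weekly_events minimum mean combined events per week
#'   (default 280).
#' @return the filtered `event_log` (possibly empty, with a warning).
#' @export
filter_participants <- function(log, min_day_fraction = 0.80,
                                min_weekly_events = 280) {
  if (nrow(log) == 0L) stop("cannot filter an empty event log")
  window <- log_window(log)
  n_days <- as.integer(window[2] - window[1]) + 1L
  n_weeks <- n_days / 7
  dt <- data.table::as.data.table(log)
  dt[, "date" := as.Date(timestamp, tz = "UTC")]
  active_days <- dt[event == "screen_on",
                    list(n_active = data.table::uniqueN(date)), by = "user"]
  totals <- dt[, list(n_total = .N), by = "user"]
  stats <- merge(totals, active_days, by = "user", all.x = TRUE)
  stats[is.na(stats$n_active), "n_active" := 0L]
  keep <- stats[stats$n_active / n_days >= min_day_fraction &
                  stats$n_total / n_weeks >= min_weekly_events, ]$user
  if (length(keep) == 0L) {
    warning("all participants removed by the inclusion filters")
  }
  event_log(dt[dt$user %in% keep, c("user", "event", "timestamp")], window)
}

#' Build one participant's normalized weekly activity profile
#'
#' Screen-on events are counted into the 168 hour-of-week bins over the whole
#' window and divided by the total count, so the profile gives the fraction
#' of the participant's screen-on events falling in each hour of the week.
#'
#' @param events POSIXct vector of one participant's screen-on timestamps.
#' @return a `weekly_profile`: list with `fractions` (length-168, sums to 1)
#'   and `total_events`.
#' @export
build_weekly_profile <- function(events) {
  if (length(events) == 0L) {
    stop("cannot build a weekly profile from zero screen-on events")
  }
  counts <- tabulate(hour_of_week(events) + 1L, nbins = N_BINS)
  structure(
    list(fractions = counts / sum(counts), total_events = length(events)),
    class = "weekly_profile"
  )
}

#' Build weekly profiles for every participant in a log
#'
#' @param log an [event_log()] (typically after [filter_participants()]).
#' @return named list of `weekly_profile`s, one per participant, in
#'   participant-id order.
#' @export
weekly_profiles <- function(log) {
  dt <- data.table::as.data.table(log)[event == "screen_on"]
  if (nrow(dt) == 0L) stop("log contains no screen-on events")
  split_times <- split(dt$timestamp, dt$user)
  lapply(split_times, build_weekly_profile)
}

#' Assemble the population profile matrix X
#'
#' @param profiles named list of `weekly_profile`s (names are participant
#'   ids), or a list plus an `ids` vector.
#' @param ids optional participant ids overriding `names(profiles)`.
#' @return N x 168 numeric matrix, rows normalized to sum 1, rownames the
#'   participant ids, colnames `h000` ... `h167`.
#' @export
assemble_matrix <- function(profiles, ids = names(profiles)) {
  if (length(profiles) == 0L) stop("no profiles to assemble")
  if (is.null(ids) || any(!nzchar(ids))) stop("profiles must carry participant ids")
  if (anyDuplicated(ids)) {
    stop("duplicate participant ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(profiles, function(p) {
    f <- if (inherits(p, "weekly_profile")) p$fractions else as.numeric(p)
    if (length(f) != N_BINS) {
      stop("profile has length ", length(f), ", expected ", N_BINS)
    }
    if (any(f < 0)) stop("profile entries must be non-negative")
    f
  })
  X <- do.call(rbind, rows)
  dimnames(X) <- list(ids, sprintf("h%03d", 0:(N_BINS - 1L)))
  X
}

#' Population-average activity rhythm
#'
#' @param X profile matrix from [assemble_matrix()].
#' @return length-168 vector, the column-wise mean of `X` (sums to 1).
#' @export
population_average <- function(X) {
  if (is.null(dim(X)) || nrow(X) < 1L) stop("X must have at least one row")
  colMeans(X)
}

#' Write / read the profile matrix CSV
#'
#' One row per participant: first column `user`, then `h000` ... `h167`.
#' @param X profile matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_profile_matrix <- function(X, path) {
  dt <- data.table::data.table(user = rownames(X))
  dt <- cbind(dt, data.table::as.data.table(X))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  dt <- data.table::fread(path)
  X <- as.matrix(dt[, -1])
  rownames(X) <- dt$user
  X
}
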