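# Synthetic screen-event logs with planted ground truth. Each simulated
# participant mixes four diurnal archetype rhythms (morning, noon, evening,
# night bumps with weekday/weekend modulation) with Dirichlet weights; their
# hourly screen-on counts follow an inhomogeneous Poisson law whose intensity
# is zeroed inside a planted nightly sleep window. Sleep and wake hours are
# coupled to the planted weights: more night weight pushes sleep later, more
# morning weight pulls wake-up earlier, more evening weight pulls sleep
# earlier — the sign structure the association stage is expected to recover.

#' The four planted diurnal archetype rhythms
#'
#' Circular-Gaussian bumps on hour-of-day repeated over the 7 days, with
#' weekend modulation: morning and noon damped to 70% on Saturday and
#' Sunday, evening damped to 70% on Friday and Saturday, night unmodulated.
#' The peaks are placed nearly equidistantly around the waking day (morning
#' 08:00, noon 13:30, evening 19:00, night 00:30) so that no pair of
#' archetypes is much more similar than any other. Each column is
#' normalized to sum 1 over the 168 bins.
#'
#' @param peak_hours named numeric vector of peak hours of day.
#' @param sd bump widths in hours (recycled across archetypes).
#' @param baseline share of each archetype's mass spread over a tapered
#'   waking-day plateau: even a person loading entirely on one archetype
#'   keeps some activity through the waking day, as phone users do. The
#'   morning/noon/evening archetypes share a 09:00-21:00 plateau; the night
#'   archetype's plateau runs 12:00-24:00, since night-oriented people are
#'   asleep through the morning.
#' @return 168 x 4 matrix with columns `morning`, `noon`, `evening`,
#'   `night`.
#' @export
diurnal_archetypes <- function(peak_hours = c(morning = 8, noon = 13.5,
                                              evening = 19, night = 0.5),
                               sd = c(1.6, 1.9, 1.9, 1.5),
                               baseline = 0.25) {
  hours <- 0:23
  sd <- rep_len(sd, length(peak_hours))
  bump <- function(mu, s) {
    d <- circular_dist_hours(hours, mu)
    exp(-d^2 / (2 * s^2))
  }
  # tapered waking-day plateaus
  day_plateau <- stats::plogis(hours - 8.5) * stats::plogis(21.5 - hours)
  late_plateau <- stats::plogis(hours - 10.5) * stats::plogis(23.9 - hours)
  # day-of-week amplitude, Monday = day 1 ... Sunday = day 7
  amp <- list(
    morning = c(1, 1, 1, 1, 1, 0.7, 0.7),
    noon    = c(1, 1, 1, 1, 1, 0.7, 0.7),
    evening = c(1, 1, 1, 1, 0.7, 0.7, 1),
    night   = rep(1, 7)
  )
  A <- sapply(seq_along(peak_hours), function(i) {
    nm <- names(peak_hours)[i]
    b <- bump(peak_hours[[i]], sd[i])
    plateau <- if (nm == "night") late_plateau else day_plateau
    daily <- (1 - baseline) * b / sum(b) + baseline * plateau / sum(plateau)
    v <- as.vector(outer(daily, amp[[nm]]))
    v / sum(v)
  })
  dimnames(A) <- list(sprintf("h%03d", 0:167), names(peak_hours))
  A
}

#' Generator configuration
#'
#' Defaults describe the study conditions the package is exercised under: a
#' 200-person cohort observed for 50 weeks starting Monday 2014-01-06 (ISO
#' weeks 2-51 of 2014) with a mean of 300 screen-on events per person-week.
#' Each person belongs to one of four soft chronotype groups (morning,
#' noon, evening, night); their mixing weights are drawn from a Dirichlet
#' centered between that group's prototype and the population mean, so the
#' population forms four overlapping clouds on the weight simplex while the
#' morning and night weight histograms stay strongly right-skewed (most
#' people carry little weight on them).
#'
#' @param n_participants number of compliant participants (default 200).
#' @param n_weeks number of observed weeks (default 50).
#' @param events_per_week_mean mean screen-on events per week (default 300).
#' @param chronotype_mix probability of belonging to each chronotype group.
#' @param prototype_weight share of the Dirichlet concentration placed on
#'   the person's own group prototype (in `[0, 1]`; higher values give
#'   tighter chronotype groups).
#' @param concentration total Dirichlet concentration; higher values give
#'   less within-person weight spread.
#' @param base_mix population-mean weight profile blended with the
#'   prototype.
#' @param archetypes 168 x 4 non-negative template matrix with unit column
#'   sums (default [diurnal_archetypes()]).
#' @param sleep_coupling list of coupling coefficients on the noon-anchored
#'   hour axis: `sleep = sleep_base + sleep_night * w_night +
#'   sleep_evening * w_evening + sleep_morning * w_morning`,
#'   `wake = wake_base + wake_morning * w_morning + wake_night * w_night`,
#'   each plus a person-level Gaussian (`person_sd`), rounded and clamped;
#'   `jitter_sd` is the day-to-day Gaussian jitter of the planted window.
#'   Higher night weight delays sleep; higher evening or morning weight
#'   advances it; higher morning weight advances wake-up.
#' @param sleep_noise `"jitter"` (default) draws per-day sleep windows with
#'   day-to-day jitter and leaves awake-hour activity Poisson; `"none"`
#'   plants the same hour-aligned window every day and guarantees at least
#'   one event in every awake hour, so sleep inference can be checked for
#'   exact recovery.
#' @param n_low_activity extra participants violating the weekly-event
#'   filter (about 100 screen-on events/week).
#' @param n_sparse_days extra participants violating the active-days filter
#'   (no activity on a random 40% of days).
#' @param start_date first observed day (a Monday).
#' @param seed master seed; the emitted log is a deterministic function of
#'   the full configuration.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_participants = 200L,
                             n_weeks = 50L,
                             events_per_week_mean = 300,
                             chronotype_mix = c(morning = 0.25, noon = 0.25,
                                                evening = 0.25, night = 0.25),
                             prototype_weight = 0.75,
                             concentration = 8,
                             base_mix = c(morning = 0.15, noon = 0.35,
                                          evening = 0.35, night = 0.15),
                             archetypes = diurnal_archetypes(),
                             sleep_coupling = list(sleep_base = 11.5,
                                                   sleep_night = 8,
                                                   sleep_evening = -2,
                                                   sleep_morning = -2,
                                                   wake_base = 20,
                                                   wake_morning = -3,
                                                   wake_night = 4,
                                                   person_sd = 0.6,
                                                   jitter_sd = 0.7),
                             sleep_noise = c("jitter", "none"),
                             n_low_activity = 0L,
                             n_sparse_days = 0L,
                             start_date = as.Date("2014-01-06"),
                             seed = 1L) {
  sleep_noise <- match.arg(sleep_noise)
  if (n_participants < 1L || n_weeks < 1L) {
    stop("need at least one participant and one week")
  }
  if (events_per_week_mean <= 0) stop("events_per_week_mean must be positive")
  if (any(chronotype_mix < 0) || abs(sum(chronotype_mix) - 1) > 1e-9) {
    stop("chronotype_mix must be a probability vector")
  }
  if (prototype_weight < 0 || prototype_weight > 1) {
    stop("prototype_weight must lie in [0, 1]")
  }
  if (concentration <= 0 || any(base_mix <= 0)) {
    stop("concentration and base_mix must be positive")
  }
  if (format(start_date, "%u") != "1") stop("start_date must be a Monday")
  archetypes <- as.matrix(archetypes)
  if (nrow(archetypes) != 168L || any(archetypes < 0) ||
      any(abs(colSums(archetypes) - 1) > 1e-9)) {
    stop("archetypes must be 168-row, non-negative, with unit column sums")
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_weeks = as.integer(n_weeks),
                 events_per_week_mean = events_per_week_mean,
                 chronotype_mix = chronotype_mix,
                 prototype_weight = prototype_weight,
                 concentration = concentration,
                 base_mix = base_mix,
                 archetypes = archetypes,
                 sleep_coupling = sleep_coupling,
                 sleep_noise = sleep_noise,
                 n_low_activity = as.integer(n_low_activity),
                 n_sparse_days = as.integer(n_sparse_days),
                 start_date = start_date,
                 seed = as.integer(seed)),
            class = "generator_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic population of screen-event logs
#'
#' @param config a [generator_config()].
#' @return list with `log` (an [event_log()]) and `truth` (planted
#'   archetypes, per-person weights, typical and per-day sleep/wake hours on
#'   the clock, and the ids of filter-compliant participants).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  A <- config$archetypes
  n_days <- 7L * config$n_weeks
  n_win <- n_days - 1L
  n_hours <- n_days * 24L
  window <- c(config$start_date, config$start_date + n_days - 1L)
  t0 <- as.numeric(as.POSIXct(paste0(format(window[1]), "T00:00:00"),
                              format = TS_FORMAT, tz = "UTC"))
  t_end <- t0 + n_days * 86400

  n_ok <- config$n_participants
  ids <- c(sprintf("p%03d", seq_len(n_ok)),
           if (config$n_low_activity > 0)
             sprintf("low%02d", seq_len(config$n_low_activity)),
           if (config$n_sparse_days > 0)
             sprintf("sparse%02d", seq_len(config$n_sparse_days)))
  n_all <- length(ids)
  cp <- config$sleep_coupling

  weights <- matrix(NA_real_, n_all, 4L,
                    dimnames = list(ids, colnames(A)))
  chronotype <- character(n_all)
  typ_sleep <- typ_wake <- typ_dur <- numeric(n_all)
  sleep_days <- wake_days <- matrix(NA_integer_, n_all, n_win)
  rows <- vector("list", n_all)

  for (i in seq_len(n_all)) {
    kind <- if (i <= n_ok) "ok"
            else if (i <= n_ok + config$n_low_activity) "low" else "sparse"
    epw <- if (kind == "low") config$events_per_week_mean / 3
           else config$events_per_week_mean
    # planted weights: chronotype group, then Dirichlet around its prototype
    type <- sample.int(4L, 1L, prob = config$chronotype_mix)
    chronotype[i] <- names(config$chronotype_mix)[type]
    alpha <- config$concentration *
      (config$prototype_weight * (seq_len(4L) == type) +
         (1 - config$prototype_weight) * config$base_mix)
    g <- stats::rgamma(4L, shape = alpha)
    w <- stats::setNames(g / sum(g), colnames(A))
    weights[i, ] <- w
    # typical sleep / wake on the noon-anchored axis
    # person-level sleep/wake times are continuous; only the per-day
    # planted windows are rounded to whole hours (the mask resolution), so
    # weekly profiles vary continuously across people within a chronotype
    s <- clamp(cp$sleep_base + cp$sleep_night * w["night"] +
                 cp$sleep_evening * w["evening"] +
                 cp$sleep_morning * w["morning"] +
                 stats::rnorm(1, 0, cp$person_sd), 7, 17)
    v <- clamp(cp$wake_base + cp$wake_morning * w["morning"] +
                 cp$wake_night * w["night"] +
                 stats::rnorm(1, 0, cp$person_sd), s + 4, 22)
    typ_sleep[i] <- anchor_to_clock(round(s))
    typ_wake[i] <- anchor_to_clock(round(v))
    typ_dur[i] <- round(v) - round(s)
    # per-day planted windows
    if (config$sleep_noise == "jitter") {
      s_d <- clamp(round(s + stats::rnorm(n_win, 0, cp$jitter_sd)), 5, 18)
      v_d <- clamp(round(v + stats::rnorm(n_win, 0, cp$jitter_sd)),
                   s_d + 2, 22)
    } else {
      s_d <- rep(round(s), n_win)
      v_d <- rep(round(v), n_win)
    }
    sleep_days[i, ] <- s_d
    wake_days[i, ] <- v_d
    # hourly intensity: archetype mixture masked by the sleep windows,
    # renormalized so the expected weekly total stays events_per_week_mean
    lam <- rep(as.vector(A %*% w), config$n_weeks)
    asleep_idx <- unlist(lapply(seq_len(n_win), function(j) {
      12L + 24L * (j - 1L) + seq.int(s_d[j], v_d[j] - 1L)
    }), use.names = FALSE)
    # partial nights at the edges of the window, from the typical hours:
    # the tail of the night preceding day 0 and the onset of the last night
    rs <- as.integer(round(s)); rv <- as.integer(round(v))
    if (rv > 12L) asleep_idx <- c(seq_len(rv - 12L) - 1L, asleep_idx)
    if (rs < 12L) {
      asleep_idx <- c(asleep_idx, seq.int(n_hours - 12L + rs, n_hours - 1L))
    }
    lam[asleep_idx + 1L] <- 0
    lam <- lam * (epw * config$n_weeks) / sum(lam)
    counts <- stats::rpois(n_hours, lam)
    if (config$sleep_noise == "none") {
      awake <- lam > 0
      counts[awake & counts == 0L] <- 1L
    }
    if (kind == "sparse") {
      off_days <- sample.int(n_days, size = round(0.4 * n_days))
      day_of_hour <- rep(seq_len(n_days), each = 24L)
      counts[day_of_hour %in% off_days] <- 0L
    }
    active <- which(counts > 0L)
    if (length(active) == 0L) next
    hrs <- rep(active - 1L, counts[active])
    on <- t0 + hrs * 3600 + stats::runif(length(hrs)) * 3600
    off <- pmin(on + stats::runif(length(hrs), 30, 300), t_end - 1)
    rows[[i]] <- data.table::data.table(
      user = ids[i],
      event = rep(c("screen_on", "screen_off"), each = length(on)),
      timestamp = c(on, off)
    )
  }
  dt <- data.table::rbindlist(rows)
  dt[, "timestamp" := as.POSIXct(timestamp, tz = "UTC",
                                 origin = "1970-01-01")]
  log <- event_log(dt, window)
  truth <- list(
    archetypes = A,
    weights = weights,
    chronotype = stats::setNames(chronotype, ids),
    typical_sleep = stats::setNames(typ_sleep, ids),
    typical_wake = stats::setNames(typ_wake, ids),
    typical_mid_sleep = stats::setNames(
      circular_midpoint(typ_sleep, typ_wake), ids),
    typical_duration = stats::setNames(typ_dur, ids),
    sleep_days = sleep_days,
    wake_days = wake_days,
    compliant = ids[seq_len(n_ok)],
    config = config
  )
  list(log = log, truth = truth)
}

#' Small degenerate event logs for edge-case tests
#'
#' @param kind one of `"empty"`, `"single_event"`, `"always_on"`,
#'   `"never_on_weekends"`; all span one week starting Monday 2014-01-06.
#' @return an [event_log()].
#' @export
degenerate_cases <- function(kind = c("empty", "single_event", "always_on",
                                      "never_on_weekends")) {
  kind <- match.arg(kind)
  start <- as.Date("2014-01-06")
  window <- c(start, start + 6L)
  t0 <- as.POSIXct(paste0(format(start), "T00:00:00"),
                   format = TS_FORMAT, tz = "UTC")
  make <- function(hours) {
    data.table::data.table(
      user = "u1", event = "screen_on",
      timestamp = t0 + hours * 3600 + 900
    )
  }
  dt <- switch(kind,
    empty = data.table::data.table(user = character(0),
                                   event = character(0),
                                   timestamp = as.POSIXct(character(0),
                                                          tz = "UTC")),
    single_event = make(10L),
    always_on = make(0:167),
    never_on_weekends = make((0:119)) # Monday 00 .. Friday 23
  )
  event_log(dt, window)
}

#' Match recovered components to planted archetypes
#'
#' Greedy best-first bipartite matching by cosine similarity between the
#' columns of the recovered component matrix and the planted archetypes.
#'
#' @param H 168 x K recovered component matrix.
#' @param archetypes 168 x K planted archetype matrix.
#' @return list with `pairs` (integer vector: `pairs[k]` is the recovered
#'   column matched to planted column `k`) and `cosine` (the matched
#'   similarities, named by archetype).
#' @export
match_components <- function(H, archetypes) {
  K <- ncol(archetypes)
  if (ncol(H) != K) stop("H and archetypes must have the same number of columns")
  S <- matrix(NA_real_, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      S[a, b] <- cosine_similarity(archetypes[, a], H[, b])
    }
  }
  pairs <- integer(K)
  cosine <- numeric(K)
  Sw <- S
  for (step in seq_len(K)) {
    best <- arrayInd(which.max(Sw), dim(Sw))
    pairs[best[1]] <- best[2]
    cosine[best[1]] <- S[best[1], best[2]]
    Sw[best[1], ] <- -Inf
    Sw[, best[2]] <- -Inf
  }
  names(cosine) <- colnames(archetypes)
  list(pairs = pairs, cosine = cosine)
}
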