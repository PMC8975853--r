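# End-to-end pipeline: filter -> profiles -> (optional) K selection -> NMF
# multistart -> weight normalization -> sleep inference -> associations,
# with every stage output serialized into a run directory and a JSON
# manifest recording seeds and counts. A single master seed deterministically
# derives all stage seeds, so a run is reproducible from
# (config, seed, input file) alone.

#' Pipeline run configuration
#'
#' Defaults reproduce the reference analysis settings: ISO weeks 2-51 of
#' 2014 (350 days), inclusion thresholds of 80% active days and 280 combined
#' events per week, 1000 NMF restarts, and a K sweep over 2..7 with 30
#' consensus runs per K.
#'
#' @param year,first_week,last_week analysis window in ISO weeks.
#' @param min_day_fraction,min_weekly_events inclusion thresholds.
#' @param K fixed number of components, or `NULL` to select it by the
#'   cophenetic sweep.
#' @param k_min,k_max sweep bounds used when `K` is `NULL`.
#' @param n_restarts NMF random restarts for the final decomposition.
#' @param tol,max_iter HALS stopping controls.
#' @param n_consensus_runs runs per K in the consensus sweep.
#' @param sleep_anchor clock hour anchoring the 24-h sleep windows.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(year = 2014L, first_week = 2L, last_week = 51L,
                       min_day_fraction = 0.80, min_weekly_events = 280,
                       K = NULL, k_min = 2L, k_max = 7L,
                       n_restarts = 1000L, tol = 1e-6, max_iter = 500L,
                       n_consensus_runs = 30L, sleep_anchor = 12L,
                       seed = 1L) {
  stopifnot(min_day_fraction >= 0, min_day_fraction <= 1,
            min_weekly_events >= 0, n_restarts >= 1, n_consensus_runs >= 2,
            sleep_anchor >= 0, sleep_anchor <= 23)
  structure(list(year = as.integer(year), first_week = as.integer(first_week),
                 last_week = as.integer(last_week),
                 min_day_fraction = min_day_fraction,
                 min_weekly_events = min_weekly_events,
                 K = if (!is.null(K)) as.integer(K),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_restarts = as.integer(n_restarts), tol = tol,
                 max_iter = as.integer(max_iter),
                 n_consensus_runs = as.integer(n_consensus_runs),
                 sleep_anchor = as.integer(sleep_anchor),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment;
#' unknown keys raise an error. Keys are the arguments of [run_config()].
#'
#' @param path path to the configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  names(args) <- keys
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @param events either a path to an event-log CSV or an [event_log()].
#' @param out_dir directory receiving all stage outputs.
#' @return the run manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, events, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  window <- analysis_window(config$year, config$first_week, config$last_week)
  log <- if (inherits(events, "event_log")) events
         else read_event_log(events, window)
  n_input <- data.table::uniqueN(log$user)

  log <- filter_participants(log, config$min_day_fraction,
                             config$min_weekly_events)
  n_retained <- data.table::uniqueN(log$user)
  write_event_log(log, file.path(out_dir, "filtered_events.csv"))

  X <- assemble_matrix(weekly_profiles(log))
  write_profile_matrix(X, file.path(out_dir, "profiles.csv"))

  seeds <- derive_seeds(config$seed, 3L, stream = 10L)
  selection <- NULL
  K <- config$K
  if (is.null(K)) {
    selection <- select_k(X, config$k_min, config$k_max,
                          n_runs = config$n_consensus_runs, seed = seeds[1])
    K <- selection$best_k
    data.table::fwrite(selection$table, file.path(out_dir, "select_k.csv"))
  }

  fit <- nmf_multistart(X, K, n_seeds = config$n_restarts, seed = seeds[2],
                        tol = config$tol, max_iter = config$max_iter)
  write_decomposition(fit, out_dir, ids = rownames(X))
  weights <- normalize_weights(fit, ids = rownames(X))
  wdt <- data.table::data.table(user = rownames(weights$weights))
  data.table::fwrite(cbind(wdt, data.table::as.data.table(weights$weights)),
                     file.path(out_dir, "normalized_weights.csv"))

  records <- infer_sleep(log, anchor = config$sleep_anchor)
  data.table::fwrite(records, file.path(out_dir, "sleep.csv"))
  summaries <- summarize_sleep_all(records)
  data.table::fwrite(summaries, file.path(out_dir, "sleep_summary.csv"))

  wcorr <- weight_correlation_matrix(weights)
  write_association_table(wcorr, file.path(out_dir, "weight_correlations.csv"))
  assoc <- sleep_weight_associations(weights, summaries)
  write_association_table(assoc, file.path(out_dir, "sleep_associations.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("screenrhythms")),
    seed = config$seed,
    stage_seeds = list(select_k = seeds[1], nmf = seeds[2]),
    window = as.character(window),
    n_participants_input = n_input,
    n_participants_retained = n_retained,
    K = K,
    k_selected_by_sweep = is.null(config$K),
    n_restarts = config$n_restarts,
    nmf_error = fit$error,
    component_labels = weights$labels,
    n_sleep_records = nrow(records),
    cophenetic = if (!is.null(selection)) {
      stats::setNames(selection$table$cophenetic,
                      paste0("K", selection$table$K))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
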