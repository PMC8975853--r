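# Internal helpers shared across modules.

#' @importFrom data.table := .N .SD
#' @importFrom stats runif rpois rgamma rnorm
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("timestamp", "event", "user", "date", "."))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic stages (the generator, NMF restarts, consensus runs) draw
#' their seeds through this function so that a single master seed determines
#' every random number in a run. Each stage uses a distinct `stream` id, so
#' changing the number of seeds requested by one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @param stream small non-negative integer identifying the consuming stage.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master, n, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(master) + 1000003L * as.integer(stream)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Map a clock hour (possibly fractional) onto the noon-anchored axis where
# 12:00 -> 0 and 11:00 -> 23, so "later in the social day" is monotone
# across midnight.
noon_anchor <- function(hour) (hour - 12) %% 24

# Inverse of noon_anchor.
anchor_to_clock <- function(anchored) (anchored + 12) %% 24

# Circular midpoint of two clock hours along the shorter arc.
circular_midpoint <- function(a, b) {
  d <- (b - a) %% 24
  ifelse(d <= 12, (a + d / 2) %% 24, (b + (24 - d) / 2) %% 24)
}

# Circular mean of clock hours (period 24); returns a real clock hour.
circular_mean_hours <- function(hours) {
  ang <- hours * 2 * pi / 24
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (m * 24 / (2 * pi)) %% 24
}

# Circular distance between clock hours (period 24).
circular_dist_hours <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# Cosine similarity between two non-negative vectors.
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
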