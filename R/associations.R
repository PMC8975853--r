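# Pearson correlations among component weights and between weights and the
# inferred sleep variables. Hour-valued sleep variables are linearized on
# the noon-anchored axis (12:00 -> 0, ..., 11:00 -> 23) before correlating,
# so "later" is monotone across midnight.

#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the t-statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `>= 3`, both non-constant.
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

new_association_table <- function(r, p) {
  structure(list(r = r, p = p), class = "association_table")
}

#' @export
print.association_table <- function(x, digits = 3, ...) {
  cat("<association_table> Pearson r:\n")
  print(round(x$r, digits))
  cat("p-values:\n")
  print(signif(x$p, digits))
  invisible(x)
}

#' Turn an association table into a long data.frame
#' @param x an `association_table`.
#' @param ... unused.
#' @return data.frame with columns `component`, `variable`, `r`, `p`.
#' @export
as.data.frame.association_table <- function(x, ...) {
  grid <- expand.grid(component = rownames(x$r), variable = colnames(x$r),
                      stringsAsFactors = FALSE)
  grid$r <- as.vector(x$r)
  grid$p <- as.vector(x$p)
  grid
}

#' Pairwise correlations between component weights
#'
#' @param weights an `nmf_weights` from [normalize_weights()], or a plain
#'   N x K weight matrix with column names.
#' @return an `association_table` with K x K matrices `r` (unit diagonal)
#'   and `p` (NA on the diagonal).
#' @export
weight_correlation_matrix <- function(weights) {
  W <- if (inherits(weights, "nmf_weights")) weights$weights else as.matrix(weights)
  if (nrow(W) < 3L) stop("need at least 3 participants")
  K <- ncol(W)
  labs <- colnames(W) %||% paste0("c", seq_len(K))
  r <- diag(1, K); p <- matrix(NA_real_, K, K)
  dimnames(r) <- dimnames(p) <- list(labs, labs)
  for (a in seq_len(K - 1L)) {
    for (b in seq.int(a + 1L, K)) {
      res <- pearson_with_p(W[, a], W[, b])
      r[a, b] <- r[b, a] <- res$r
      p[a, b] <- p[b, a] <- res$p
    }
  }
  new_association_table(r, p)
}

#' Correlations between component weights and sleep variables
#'
#' Builds the components x (sleep time, mid-sleep time, wake-up time, sleep
#' duration) grid of Pearson r and p. Sleep, mid-sleep and wake hours are
#' mapped to the noon-anchored axis before correlating.
#'
#' @param weights an `nmf_weights` (rownames are participant ids) or a
#'   weight matrix with rownames.
#' @param summaries data.frame from [summarize_sleep_all()] with columns
#'   `user`, `typical_sleep`, `typical_wake`, `typical_mid_sleep`,
#'   `mean_duration`.
#' @return an `association_table` (K x 4).
#' @export
sleep_weight_associations <- function(weights, summaries) {
  W <- if (inherits(weights, "nmf_weights")) weights$weights else as.matrix(weights)
  ids <- rownames(W)
  if (is.null(ids)) stop("weights must carry participant ids as rownames")
  summaries <- as.data.frame(summaries)
  unmatched <- c(setdiff(ids, summaries$user), setdiff(summaries$user, ids))
  if (length(unmatched)) {
    stop("participant ids not matched between weights and sleep summaries: ",
         paste(unmatched, collapse = ", "))
  }
  summaries <- summaries[match(ids, summaries$user), ]
  vars <- cbind(
    sleep_time = noon_anchor(summaries$typical_sleep),
    mid_sleep_time = noon_anchor(summaries$typical_mid_sleep),
    wake_time = noon_anchor(summaries$typical_wake),
    sleep_duration = summaries$mean_duration
  )
  K <- ncol(W)
  labs <- colnames(W) %||% paste0("c", seq_len(K))
  r <- matrix(NA_real_, K, 4L, dimnames = list(labs, colnames(vars)))
  p <- r
  for (a in seq_len(K)) {
    for (b in seq_len(4L)) {
      res <- pearson_with_p(W[, a], vars[, b])
      r[a, b] <- res$r
      p[a, b] <- res$p
    }
  }
  new_association_table(r, p)
}

#' Write an association table as a long CSV
#'
#' Columns `component,variable,r,p`, one row per cell.
#' @param tab an `association_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path)
  invisible(path)
}
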