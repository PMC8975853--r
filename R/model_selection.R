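# Choosing the number of NMF components K by consensus clustering: across
# repeated randomly initialized runs, participants are assigned to their
# dominant component; the stability of co-assignments is summarized by the
# cophenetic correlation coefficient of the consensus matrix, and K is the
# sweep value maximizing it.

#' Consensus matrix over repeated NMF runs
#'
#' For each of `n_runs` independently initialized NMF runs at rank `K`,
#' every participant is assigned to the component carrying their largest
#' normalized weight (ties to the lowest component index). Entry `(i, j)` of
#' the consensus matrix is the fraction of runs in which participants `i` and
#' `j` share an assignment.
#'
#' Each run uses the classical multiplicative updates
#' ([nmf_multiplicative()]) for a modest, fixed number of iterations — the
#' convention of consensus-based rank selection. Run-to-run variability
#' under random initialization is exactly the signal the consensus matrix
#' measures; HALS run to convergence finds essentially the same factors
#' from any start and would mask it.
#'
#' @param X profile matrix (participants x 168).
#' @param K rank of each run.
#' @param n_runs number of runs (default 30, must be >= 2).
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param max_iter multiplicative-update iterations per run (default 30).
#' @return a `consensus_result`: list with `K`, `consensus` (N x N, unit
#'   diagonal, entries in \[0, 1\]), `cophenetic` (NA until computed),
#'   `n_runs`.
#' @export
consensus_matrix <- function(X, K, n_runs = 30L, seed = 1L,
                             max_iter = 30L) {
  if (n_runs < 2L) stop("n_runs must be >= 2")
  X <- as.matrix(X)
  N <- nrow(X)
  seeds <- derive_seeds(seed, n_runs, stream = 2L)
  C <- matrix(0, N, N)
  for (r in seq_len(n_runs)) {
    fit <- nmf_multiplicative(X, K, seed = seeds[r], max_iter = max_iter)
    # argmax of the normalized weight; row normalization does not change the
    # argmax, so scaling W columns by the H column masses suffices
    scaled <- sweep(fit$W, 2, colSums(fit$H), "*")
    assign <- max.col(scaled, ties.method = "first")
    if (length(unique(assign)) == 1L) {
      warning(sprintf("consensus run %d at K=%d: one component captured all participants",
                      r, K))
    }
    C <- C + outer(assign, assign, "==")
  }
  C <- C / n_runs
  diag(C) <- 1
  structure(list(K = as.integer(K), consensus = C, cophenetic = NA_real_,
                 n_runs = as.integer(n_runs)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> K = %d, n_runs = %d, cophenetic = %s\n",
              x$K, x$n_runs,
              if (is.na(x$cophenetic)) "not computed" else
                sprintf("%.4f", x$cophenetic)))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' The dissimilarity `D = 1 - consensus` is clustered with average-linkage
#' hierarchical clustering; the coefficient is the Pearson correlation
#' between the off-diagonal entries of `D` and the cophenetic distances of
#' the dendrogram. Values near 1 indicate stable, well-separated clustering.
#'
#' @param consensus N x N consensus matrix (or a `consensus_result`).
#' @return the coefficient, a real in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  if (inherits(consensus, "consensus_result")) consensus <- consensus$consensus
  C <- as.matrix(consensus)
  N <- nrow(C)
  if (N < 3L) stop("cophenetic coefficient needs at least 3 items")
  if (max(abs(C - t(C))) > 1e-12) stop("consensus matrix must be symmetric")
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0) {
    stop("cophenetic coefficient undefined: zero variance in distances")
  }
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  r <- stats::cor(as.vector(d), as.vector(coph))
  if (is.na(r)) {
    stop("cophenetic coefficient undefined: degenerate dendrogram distances")
  }
  r
}

#' Select the number of components K
#'
#' Sweeps `K` from `k_min` to `k_max`, computing a consensus matrix
#' ([consensus_matrix()]) and its cophenetic coefficient for each, and
#' returns the smallest `K` attaining the maximum coefficient.
#'
#' @inheritParams consensus_matrix
#' @param k_min,k_max sweep bounds, `2 <= k_min < k_max <= min(N, 168)`.
#' @return a `k_selection`: list with `table` (data.frame of K and
#'   cophenetic), `best_k`, and `results` (the per-K `consensus_result`s).
#' @export
select_k <- function(X, k_min = 2L, k_max = 7L, n_runs = 30L, seed = 1L,
                     max_iter = 30L) {
  X <- as.matrix(X)
  kmax_allowed <- min(nrow(X), ncol(X))
  if (!(2L <= k_min && k_min < k_max && k_max <= kmax_allowed)) {
    stop(sprintf("invalid sweep range: need 2 <= k_min < k_max <= %d",
                 kmax_allowed))
  }
  ks <- seq.int(k_min, k_max)
  sub_seeds <- derive_seeds(seed, length(ks), stream = 3L)
  results <- vector("list", length(ks))
  coph <- numeric(length(ks))
  for (i in seq_along(ks)) {
    res <- consensus_matrix(X, ks[i], n_runs = n_runs, seed = sub_seeds[i],
                            max_iter = max_iter)
    res$cophenetic <- cophenetic_coefficient(res$consensus)
    results[[i]] <- res
    coph[i] <- res$cophenetic
  }
  best <- ks[which.max(coph)] # which.max returns the first (smallest K) max
  structure(list(table = data.frame(K = ks, cophenetic = coph),
                 best_k = best, results = results),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected K = %d\n", x$best_k))
  invisible(x)
}
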