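# Independent oracles used to cross-check the package's own implementations.
# These deliberately share no code with the functions they verify.

# Lee-Seung multiplicative updates for the Frobenius NMF objective, from a
# seeded random start, run until the objective stops improving (or max_iter).
mu_nmf_oracle <- function(X, K, seed, max_iter = 200000, rel_tol = 1e-13) {
  set.seed(seed)
  N <- nrow(X); M <- ncol(X)
  s <- sqrt(mean(X) / K)
  W <- matrix(runif(N * K, 0, s), N, K)
  H <- matrix(runif(M * K, 0, s), M, K)
  err <- 0.5 * sum((X - tcrossprod(W, H))^2)
  for (it in seq_len(max_iter)) {
    W <- W * (X %*% H) / pmax(W %*% crossprod(H), 1e-300)
    H <- H * crossprod(X, W) / pmax(H %*% crossprod(W), 1e-300)
    if (it %% 100 == 0) {
      new_err <- 0.5 * sum((X - tcrossprod(W, H))^2)
      if (err - new_err < rel_tol * max(err, 1e-300)) { err <- new_err; break }
      err <- new_err
    }
  }
  list(W = W, H = H, error = 0.5 * sum((X - tcrossprod(W, H))^2))
}

# Brute-force cophenetic coefficient: performs average-linkage agglomeration
# explicitly on the full distance matrix, records the merge height at which
# every pair first joins, and correlates those heights with the off-diagonal
# distances.
brute_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, length(members))
  coph <- matrix(NA_real_, n, n)
  # average-linkage distance between two member sets from the original D
  avg_link <- function(a, b) mean(D[a, b, drop = FALSE])
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        d <- avg_link(members[[idx[ii]]], members[[idx[jj]]])
        if (d < best_d) { best_d <- d; best <- c(idx[ii], idx[jj]) }
      }
    }
    a <- members[[best[1]]]; b <- members[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    members[[best[1]]] <- c(a, b)
    active[best[2]] <- FALSE
  }
  lower <- lower.tri(D)
  stats::cor(D[lower], coph[lower])
}

# Exact two-sided permutation p-value for the Pearson correlation: enumerates
# all n! orderings of y (only usable for tiny n).
permutation_pearson_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  r_obs <- stats::cor(x, y)
  rs <- vapply(perms(y), function(p) stats::cor(x, p), numeric(1))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Shared synthetic populations, generated once per test session.
tiny_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_population(
        generator_config(n_participants = 30, n_weeks = 8, seed = 421))
    }
    cache
  }
})

# The default study population: generator_config() defaults (200 people,
# 50 weeks, master seed 1).
default_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_population(generator_config())
    cache
  }
})
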