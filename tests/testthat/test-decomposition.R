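test_that("HALS recovers an exact non-negative low-rank factorization", {
  set.seed(1)
  w <- c(1, 2, 3, 0.5, 1.5, 2.5)
  h <- c(0.2, 0, 1, 0.5, 0.1, 0, 0.7, 0.3)
  X <- outer(w, h)
  fit <- nmf_hals(X, K = 1, seed = 42, tol = 0, max_iter = 300)
  expect_lt(fit$error, 1e-10)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("HALS handles the all-zero matrix", {
  fit <- nmf_hals(matrix(0, 5, 6), K = 2)
  expect_identical(fit$error, 0)
  expect_equal(tcrossprod(fit$W, fit$H), matrix(0, 5, 6))
})

test_that("HALS validates its inputs", {
  X <- matrix(abs(rnorm(12)), 3, 4)
  expect_error(nmf_hals(X, K = 0), "K must lie")
  expect_error(nmf_hals(X, K = 5), "K must lie")
  expect_error(nmf_hals(-X, K = 2), "non-negative")
})

test_that("HALS error is non-increasing across sweeps", {
  set.seed(7)
  for (rep in 1:5) {
    X <- matrix(abs(rnorm(20 * 12)), 20, 12)
    fit <- nmf_hals(X, K = 3, seed = rep, tol = 0, max_iter = 80)
    expect_true(all(diff(fit$error_trace) <= 1e-12))
  }
})

test_that("stored error matches the objective recomputed from the factors", {
  set.seed(2)
  X <- matrix(abs(rnorm(15 * 10)), 15, 10)
  fit <- nmf_hals(X, K = 2, seed = 9)
  recomputed <- 0.5 * sum((X - tcrossprod(fit$W, fit$H))^2)
  expect_equal(fit$error, recomputed, tolerance = 1e-8)
})

test_that("HALS matches a multiplicative-update oracle on planted factors", {
  set.seed(11)
  W0 <- matrix(rexp(6 * 2), 6, 2)
  H0 <- matrix(rexp(8 * 2), 8, 2)
  X <- tcrossprod(W0, H0)
  hals <- nmf_hals(X, K = 2, seed = 5, tol = 0, max_iter = 2000)
  mu <- mu_nmf_oracle(X, K = 2, seed = 5)
  # both routes should reach (numerically) the exact factorization
  expect_lt(abs(hals$error - mu$error), 1e-6)
  expect_lt(hals$error, 1e-8)
})

test_that("multistart returns the best of its restarts, reproducibly", {
  set.seed(3)
  X <- matrix(abs(rnorm(12 * 9)), 12, 9)
  one <- nmf_multistart(X, K = 2, n_seeds = 1, seed = 17)
  again <- nmf_multistart(X, K = 2, n_seeds = 1, seed = 17)
  expect_identical(one$W, again$W)
  expect_identical(one$error, again$error)

  multi <- nmf_multistart(X, K = 2, n_seeds = 10, seed = 17)
  expect_length(multi$restart_errors, 10)
  expect_identical(multi$error, min(multi$restart_errors))
})

test_that("with enough restarts the best error beats the median run", {
  pop <- tiny_population()
  X <- assemble_matrix(weekly_profiles(pop$log))
  multi <- nmf_multistart(X, K = 4, n_seeds = 20, seed = 31)
  expect_lte(multi$error, stats::median(multi$restart_errors))
})

test_that("normalize_weights yields unit row sums without changing W H^T", {
  set.seed(5)
  X <- matrix(abs(rnorm(10 * 8)), 10, 8)
  fit <- nmf_hals(X, K = 3, seed = 2)
  approx_before <- tcrossprod(fit$W, fit$H)
  # column rescaling must leave the approximation invariant; use raw parts
  mass <- colSums(fit$H)
  W2 <- sweep(fit$W, 2, mass, "*")
  H2 <- sweep(fit$H, 2, mass, "/")
  expect_equal(tcrossprod(W2, H2), approx_before, tolerance = 1e-9)

  Xp <- assemble_matrix(weekly_profiles(tiny_population()$log))
  nf <- nmf_multistart(Xp, K = 4, n_seeds = 3, seed = 8)
  w <- normalize_weights(nf, ids = rownames(Xp))
  expect_equal(unname(rowSums(w$weights)), rep(1, nrow(Xp)), tolerance = 1e-9)
  expect_true(all(w$weights >= 0 & w$weights <= 1))
})

test_that("a simple two-weight normalization matches the hand result", {
  fit <- list(W = rbind(c(2, 2), c(1, 3)),
              H = matrix(rep(0.25, 8), 4, 2), K = 2)
  class(fit) <- "nmf_fit"
  w <- normalize_weights(fit, ids = c("a", "b"))
  expect_equal(unname(w$weights["a", ]), c(0.5, 0.5))
  expect_equal(unname(w$weights["b", ]), c(0.25, 0.75))
})

test_that("normalize_weights reports the participant with an all-zero row", {
  fit <- list(W = rbind(c(1, 1), c(0, 0)),
              H = matrix(rep(0.25, 8), 4, 2), K = 2)
  class(fit) <- "nmf_fit"
  expect_error(normalize_weights(fit, ids = c("ok", "dead")), "dead")
})

test_that("components are labeled by their diurnal peak band", {
  one_hot <- function(hour) {
    v <- rep(0, 168)
    v[hour + 1 + 24 * (0:6)] <- 1
    v
  }
  H <- cbind(one_hot(8), one_hot(23), one_hot(12), one_hot(18))
  expect_identical(label_components(H), c("morning", "night", "noon", "evening"))
  # two components peaking in the same band get ordinal suffixes by peak hour
  H2 <- cbind(one_hot(9), one_hot(6), one_hot(13))
  expect_identical(label_components(H2), c("morning.2", "morning.1", "noon"))
  expect_identical(component_peak_hours(H2), c(9L, 6L, 13L))
})

test_that("planted archetypes are recovered from a mid-sized population", {
  pop <- tiny_population()
  X <- assemble_matrix(weekly_profiles(pop$log))
  fit <- nmf_multistart(X, K = 4, n_seeds = 8, seed = 12)
  w <- normalize_weights(fit, ids = rownames(X))
  m <- match_components(w$H, pop$truth$archetypes)
  expect_true(all(m$cosine > 0.85)) # full-scale bound (0.90) checked at N=200
  expect_setequal(m$pairs, 1:4)
})

test_that("decomposition serialization round-trips through CSV + JSON", {
  X <- assemble_matrix(weekly_profiles(tiny_population()$log))
  fit <- nmf_hals(X, K = 3, seed = 4)
  dir <- withr::local_tempdir()
  write_decomposition(fit, dir, ids = rownames(X))
  W <- data.table::fread(file.path(dir, "W.csv"))
  H <- data.table::fread(file.path(dir, "H.csv"))
  meta <- jsonlite::read_json(file.path(dir, "decomposition.json"))
  expect_identical(W$user, rownames(X))
  expect_equal(as.matrix(W[, -1]), fit$W, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(nrow(H), 168L)
  expect_identical(meta$K, 3L)
  expect_equal(meta$error, fit$error, tolerance = 1e-12)
})
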