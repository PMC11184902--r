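test_that("edge weights are absolute correlations with sign invariance", {
  set.seed(21)
  n <- 6
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- cbind(X[, 1], -X[, 2], rnorm(n))
  d <- paired_omics(X, Y, c(0, 0, 0, 1, 1, 1))

  Wp <- edge_weights(d, method = "pooled")
  expect_equal(Wp[1, 1], 1)           # identical column
  expect_equal(Wp[2, 2], 1)           # negated column
  expect_true(all(Wp >= 0 & Wp <= 1 + 1e-12))
  for (i in 1:3) for (j in 1:3)
    expect_equal(Wp[i, j], abs(brute_pearson(X[, i], Y[, j])),
                 tolerance = 1e-12)

  Wg <- edge_weights(d, method = "group_max")
  i0 <- d$z == 0
  for (i in 1:3) for (j in 1:3)
    expect_equal(Wg[i, j],
                 max(abs(brute_pearson(X[i0, i], Y[i0, j])),
                     abs(brute_pearson(X[!i0, i], Y[!i0, j]))),
                 tolerance = 1e-12)
})

test_that("group_max weights expose associations that cancel in the pool", {
  # opposite-sign association in the two groups: pooled correlation ~0,
  # group-wise correlations strong
  d <- toy_differential_data(n_per_group = 100, noise_sd = 0.2, seed = 3)
  Wp <- edge_weights(d, "pooled")
  Wg <- edge_weights(d, "group_max")
  # within-group correlation of Y1 with X1 is ~ 1/sqrt(2 + noise_sd^2)
  expect_lt(Wp[1, 1], 0.25)
  expect_gt(Wg[1, 1], 0.6)
})

test_that("binarization is a strict threshold", {
  W <- matrix(c(0.5, 0.3, 0.3, 0), 2, 2)
  expect_equal(binarize(W, 0.3), matrix(c(1, 0, 0, 0), 2, 2))
  expect_true(all(binarize(matrix(0, 3, 3), 0) == 0))
  expect_error(binarize(W, 1), "\\[0, 1\\)")
  expect_error(binarize(W, -0.1), "\\[0, 1\\)")
})

test_that("biclique objective equals count over area^lambda", {
  A1 <- matrix(1, 3, 3)
  expect_equal(biclique_objective(A1, 1:3, 1:3, 1), 1)
  expect_equal(biclique_objective(A1, 1:3, 1:3, 0.5), 3)
  set.seed(4)
  A <- matrix(rbinom(25, 1, 0.4), 5, 5)
  nx <- c(1, 3, 4); ny <- c(2, 5)
  for (lam in c(0.5, 1, 1.3))
    expect_equal(biclique_objective(A, nx, ny, lam),
                 sum(A[nx, ny]) / (length(nx) * length(ny))^lam)
  expect_error(biclique_objective(A, integer(0), ny, 1), "non-empty")
})

test_that("greedy extraction finds planted blocks and matches enumeration", {
  # all-ones matrix: for lambda < 1 the full node sets win
  A <- matrix(1, 4, 4)
  bc <- greedy_quasi_biclique(A, lambda_k = 0.5)
  expect_equal(bc$nx, 1:4)
  expect_equal(bc$ny, 1:4)
  expect_equal(bc$objective, 16 / 4)

  # planted 3x3 all-ones block in an 8x8 zero matrix
  A <- matrix(0, 8, 8)
  A[2:4, 5:7] <- 1
  bc <- greedy_quasi_biclique(A, lambda_k = 0.5)
  expect_equal(bc$nx, 2:4)
  expect_equal(bc$ny, 5:7)
  opt <- enum_best_biclique(A, 0.5)
  expect_equal(bc$objective, opt$objective)

  # a second planted 2x2 block is found after excluding the first
  A[7:8, 1:2] <- 1
  bc1 <- greedy_quasi_biclique(A, lambda_k = 0.5)
  expect_equal(bc1$nx, 2:4)
  bc2 <- greedy_quasi_biclique(A, excluded_x = bc1$nx,
                               excluded_y = bc1$ny, lambda_k = 0.5)
  expect_equal(bc2$nx, 7:8)
  expect_equal(bc2$ny, 1:2)
  Ares <- A; Ares[bc1$nx, ] <- 0; Ares[, bc1$ny] <- 0
  expect_equal(bc2$objective, enum_best_biclique(Ares, 0.5)$objective)

  # determinism and the empty-graph signal
  expect_identical(greedy_quasi_biclique(A, lambda_k = 0.5),
                   greedy_quasi_biclique(A, lambda_k = 0.5))
  expect_null(greedy_quasi_biclique(matrix(0, 5, 5), lambda_k = 1))
  expect_null(greedy_quasi_biclique(A, excluded_x = 1:8, lambda_k = 1))
})

test_that("greedy solution is optimal on random noiseless-style instances", {
  # exhaustive enumeration oracle on small random matrices: the greedy
  # objective can in principle fall short of the optimum (local search),
  # but must never exceed it, and on clearly planted instances it attains it
  set.seed(11)
  ratios <- replicate(20, {
    A <- matrix(rbinom(36, 1, 0.3), 6, 6)
    if (sum(A) == 0) return(NA_real_)
    bc <- greedy_quasi_biclique(A, lambda_k = 0.8)
    bc$objective / enum_best_biclique(A, 0.8)$objective
  })
  ratios <- ratios[!is.na(ratios)]
  expect_true(all(ratios <= 1 + 1e-12))
  expect_gt(mean(ratios), 0.8)
})

test_that("Bernoulli mixture MLEs are the sample proportions", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3][1:6] <- 1              # 6 ones inside the 3x3 block
  A[5, 5] <- 1; A[6, 6] <- 1         # 2 ones among the 27 outside cells
  fit <- bernoulli_mle(A, 1:3, 1:3)
  expect_equal(fit$pi1, 6 / 9)
  expect_equal(fit$pi0, 2 / 27)
  expect_equal(fit$pi, 8 / 36)

  z <- bernoulli_mle(matrix(0, 4, 4), 1:2, 1:2)
  expect_equal(c(z$pi, z$pi0, z$pi1), c(0, 0, 0))
  expect_equal(z$kl, 0)

  # uniform random matrix: block and non-block densities agree to
  # within binomial error (10,000 cells)
  set.seed(5)
  A <- matrix(rbinom(10000, 1, 0.3), 100, 100)
  fit <- bernoulli_mle(A, 1:30, 1:30)
  se <- sqrt(0.3 * 0.7 * (1 / 900 + 1 / 9100))
  expect_lt(abs(fit$pi1 - fit$pi0), 4 * se)

  expect_error(bernoulli_mle(A, 1:100, 1:100), "outside")
})

test_that("KL divergence follows the printed mixture formula", {
  # no contrast: all probabilities equal -> 0
  A <- matrix(rbinom(25, 1, 0.5), 5, 5)
  fit <- structure(list(pi = 0.4, pi0 = 0.4, pi1 = 0.4),
                   class = "bernoulli_mixture_fit")
  expect_equal(kl_divergence(fit, A, 1:2, 1:2), 0)

  # single in-block cell with A = 1: only the pi1*log(pi1/pi) term remains
  A1 <- matrix(1, 1, 1)
  fit1 <- structure(list(pi = 0.5, pi0 = 0.5, pi1 = 0.8),
                    class = "bernoulli_mixture_fit")
  expect_equal(kl_divergence(fit1, A1, 1, 1), 0.8 * log(0.8 / 0.5),
               tolerance = 1e-12)

  # sharper block contrast strictly increases the divergence
  set.seed(6)
  mk <- function(p1, p0) {
    A <- matrix(rbinom(400, 1, p0), 20, 20)
    A[1:6, 1:6] <- rbinom(36, 1, p1)
    bernoulli_mle(A, 1:6, 1:6)$kl
  }
  kls <- c(mk(0.55, 0.45), mk(0.75, 0.25), mk(0.95, 0.05))
  expect_true(all(diff(kls) > 0))
})

test_that("KL-based exponent selection recovers a planted block", {
  expect_equal(select_lambda_k(diag(4), grid = 0.7)$lambda_k, 0.7)

  # planted 10x20 block (the benchmark's first-block size), pi1 = 0.9
  # inside vs pi0 = 0.05 outside: the selected biclique overlaps the
  # planted block (Jaccard > 0.9 per side) in at least 95 of 100 runs
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    A <- matrix(rbinom(60 * 80, 1, 0.05), 60, 80)
    A[1:10, 1:20] <- rbinom(200, 1, 0.9)
    res <- select_lambda_k(A)
    jx <- jaccard(res$biclique$nx, 1:10)
    jy <- jaccard(res$biclique$ny, 1:20)
    if (min(jx, jy) > 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  # no block structure: the best blob the greedy can carve out of i.i.d.
  # noise carries far less divergence than a genuine planted block
  set.seed(12)
  A_flat <- matrix(rbinom(1200, 1, 0.1), 30, 40)
  A_block <- A_flat; A_block[1:6, 1:8] <- rbinom(48, 1, 0.95)
  kl_flat <- select_lambda_k(A_flat)$kl
  kl_block <- select_lambda_k(A_block)$kl
  expect_lt(kl_flat, 0.4 * kl_block)
})

test_that("screening recovers planted coefficient blocks and shrinks dims", {
  set.seed(31)
  n <- 300; p <- 60; q <- 80
  z <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(0, p, q)
  B[1:8, 1:12] <- 1
  B[9:12, 13:18] <- 1
  Y <- matrix(rnorm(n * q, sd = 0.3), n, q)
  sgn <- ifelse(z == 0, 1, -1)
  Y <- Y + sgn * (X %*% B)
  d <- standardize_columns(paired_omics(X, Y, z))

  scr <- screen_bicliques(d)
  expect_s3_class(scr, "bipartite_screen")
  expect_equal(length(scr$bicliques), 2L)
  # all planted features retained, few if any bystanders picked up
  expect_true(all(1:12 %in% scr$retained_x))
  expect_true(all(1:18 %in% scr$retained_y))
  expect_lte(length(setdiff(scr$retained_x, 1:12)), 3L)
  expect_lte(length(setdiff(scr$retained_y, 1:18)), 3L)
  # genuine dimension reduction
  expect_lt(length(scr$retained_x), p)
  expect_lt(length(scr$retained_y), q)
  # side-disjointness across bicliques
  expect_length(intersect(scr$bicliques[[1]]$nx, scr$bicliques[[2]]$nx), 0)
  expect_length(intersect(scr$bicliques[[1]]$ny, scr$bicliques[[2]]$ny), 0)
  # retained sets are the unions of the biclique node sets
  expect_setequal(scr$retained_x, unlist(lapply(scr$bicliques, `[[`, "nx")))
  expect_setequal(scr$retained_y, unlist(lapply(scr$bicliques, `[[`, "ny")))

  # exports parse and are consistent
  tab <- screen_table(scr)
  expect_setequal(tab$feature[tab$side == "X"], d$x_names[scr$retained_x])
  el <- screen_edge_list(scr)
  expect_true(all(el$weight > scr$r))

  # pure-noise data yield an empty or near-empty screen
  set.seed(32)
  dn <- paired_omics(matrix(rnorm(200 * 40), 200, 40),
                     matrix(rnorm(200 * 50), 200, 50),
                     rep(0:1, each = 100))
  scrn <- screen_bicliques(dn)
  expect_lte(length(scrn$retained_x), 5L)

  # max_blocks = 0 gives an empty screen
  scr0 <- screen_bicliques(d, max_blocks = 0)
  expect_length(scr0$bicliques, 0)
  expect_length(scr0$retained_x, 0)
})
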