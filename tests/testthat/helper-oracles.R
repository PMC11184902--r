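# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own linear-algebra paths.

# Entry-wise sample covariance via an explicit double loop, denominator m - 1.
brute_cov <- function(A, B) {
  out <- matrix(NA_real_, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      a <- A[, i]; b <- B[, j]
      out[i, j] <- sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1)
    }
  }
  out
}

# Pearson correlation from first principles for a single pair.
brute_pearson <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
}

# Exhaustive enumeration of the quasi-biclique objective over all non-empty
# node subsets; feasible up to ~8x8.
enum_best_biclique <- function(A, lambda_k) {
  p <- nrow(A); q <- ncol(A)
  stopifnot(p <= 10, q <= 10)
  subsets <- function(k) lapply(seq_len(2^k - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  best <- -Inf; best_nx <- NULL; best_ny <- NULL
  for (xs in subsets(p)) {
    cs <- colSums(A[xs, , drop = FALSE])
    for (ys in subsets(q)) {
      obj <- sum(cs[ys]) / (length(xs) * length(ys))^lambda_k
      if (obj > best) { best <- obj; best_nx <- xs; best_ny <- ys }
    }
  }
  list(objective = best, nx = best_nx, ny = best_ny)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# A small paired dataset with a planted differential block:
# Y block columns = sign_g * X block sum + noise.
toy_differential_data <- function(n_per_group = 30, p = 6, q = 8,
                                  bx = 2, by = 3, c0 = 1, c1 = -1,
                                  noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  z <- rep(c(0, 1), each = n_per_group)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q, sd = noise_sd), n, q)
  B <- matrix(0, p, q)
  B[seq_len(bx), seq_len(by)] <- 1
  Y[z == 0, ] <- Y[z == 0, ] + c0 * (X[z == 0, ] %*% B)
  Y[z == 1, ] <- Y[z == 1, ] + c1 * (X[z == 1, ] %*% B)
  paired_omics(X, Y, z)
}
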