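test_that("loading aligns rows by sample ID and validates the inputs", {
  dir <- withr::local_tempdir()
  set.seed(42)
  ids <- paste0("s", 1:6)
  X <- matrix(rnorm(18), 6, 3, dimnames = list(ids, c("mirA", "mirB", "mirC")))
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(ids, c("gene1", "gene2")))
  z <- c(0, 0, 0, 1, 1, 1)

  write.table(data.frame(sample_id = ids, X), file.path(dir, "X.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = ids, Y), file.path(dir, "Y.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = ids, group = z),
              file.path(dir, "z.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)

  d <- load_paired_data(file.path(dir, "X.tsv"), file.path(dir, "Y.tsv"),
                        file.path(dir, "z.tsv"))
  expect_s3_class(d, "paired_omics")
  expect_equal(unname(dim(d)), c(6L, 3L, 2L))
  expect_equal(d$x_names, c("mirA", "mirB", "mirC"))

  # shuffled Y rows must come back identical after ID alignment
  shuf <- sample(6)
  write.table(data.frame(sample_id = ids[shuf], Y[shuf, , drop = FALSE]),
              file.path(dir, "Y2.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  d2 <- load_paired_data(file.path(dir, "X.tsv"), file.path(dir, "Y2.tsv"),
                         file.path(dir, "z.tsv"))
  expect_equal(d2$Y, d$Y)

  # CSV dialect is auto-detected
  write.csv(data.frame(sample_id = ids, Y), file.path(dir, "Y.csv"),
            row.names = FALSE, quote = FALSE)
  d3 <- load_paired_data(file.path(dir, "X.tsv"), file.path(dir, "Y.csv"),
                         file.path(dir, "z.tsv"))
  expect_equal(d3$Y, d$Y)

  # non-binary group label
  write.table(data.frame(sample_id = ids, group = c(0, 0, 0, 1, 1, 2)),
              file.path(dir, "zbad.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(load_paired_data(file.path(dir, "X.tsv"),
                                file.path(dir, "Y.tsv"),
                                file.path(dir, "zbad.tsv")),
               "binary")

  # mismatched IDs are named in the error
  write.table(data.frame(sample_id = c(ids[-6], "s99"), Y),
              file.path(dir, "Ybad.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(load_paired_data(file.path(dir, "X.tsv"),
                                file.path(dir, "Ybad.tsv"),
                                file.path(dir, "z.tsv")),
               "s99")

  # constant columns are named in the error
  Xc <- X; Xc[, 2] <- 7
  write.table(data.frame(sample_id = ids, Xc), file.path(dir, "Xc.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_paired_data(file.path(dir, "Xc.tsv"),
                                file.path(dir, "Y.tsv"),
                                file.path(dir, "z.tsv")),
               "mirB")
})

test_that("constructor rejects degenerate inputs", {
  X <- matrix(rnorm(20), 5, 4)
  Y <- matrix(rnorm(15), 5, 3)
  expect_error(paired_omics(X, Y, c(0, 0, 0, 0, 1)), "at least 2 samples")
  expect_error(paired_omics(X[1:3, ], Y[1:3, ], c(0, 0, 1)), "4 samples")
  Xna <- X; Xna[2, 2] <- NA
  expect_error(paired_omics(Xna, Y, c(0, 0, 0, 1, 1)), "missing")
  expect_error(paired_omics(X, Y, c(0, 0, 0, 1, 1),
                            x_names = c("a", "a", "b", "c")),
               "duplicated")
})

test_that("standardization centers and scales with denominator n - 1", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(0, 10, 20, 5))
  Y <- cbind(g = c(2, 4, 6, 9))
  d <- paired_omics(X, Y, c(0, 0, 1, 1))
  s <- standardize_columns(d)
  # sd of (1,2,3) with denominator n-1 is 1, so first three entries map
  # through (x - mean)/sd directly
  expect_equal(unname(s$X[, "a"]),
               (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)))
  expect_true(all(abs(colMeans(s$X)) < 1e-12))
  expect_true(all(abs(colMeans(s$Y)) < 1e-12))
  expect_equal(unname(apply(s$X, 2, sd)), c(1, 1))

  # idempotence
  s2 <- standardize_columns(s)
  expect_equal(s2$X, s$X, tolerance = 1e-12)

  # per-group scope: means vanish within each group
  sg <- standardize_columns(d, "per_group")
  for (g in 0:1) {
    expect_true(all(abs(colMeans(sg$X[sg$z == g, , drop = FALSE])) < 1e-12))
  }
  # zero within-group variance triggers an error under per_group
  dbad <- paired_omics(cbind(c(1, 1, 2, 3), c(5, 6, 7, 8)),
                       Y, c(0, 0, 1, 1))
  expect_error(standardize_columns(dbad, "per_group"), "zero variance")
})

test_that("grouped covariances match a brute-force per-entry oracle", {
  set.seed(7)
  n <- 6
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- matrix(rnorm(n * 3), n, 3)
  z <- c(0, 0, 0, 1, 1, 1)
  d <- standardize_columns(paired_omics(X, Y, z))
  cv <- grouped_covariances(d)

  i0 <- z == 0; i1 <- z == 1
  expect_equal(unname(cv$sigma_xy), brute_cov(d$X, d$Y))
  expect_equal(unname(cv$sigma_x0y0), brute_cov(d$X[i0, ], d$Y[i0, ]))
  expect_equal(unname(cv$sigma_x1y1), brute_cov(d$X[i1, ], d$Y[i1, ]))
  expect_equal(unname(cv$sigma_x), brute_cov(d$X, d$X))
  expect_equal(unname(cv$sigma_x0), brute_cov(d$X[i0, ], d$X[i0, ]))
  expect_equal(unname(cv$sigma_x1), brute_cov(d$X[i1, ], d$X[i1, ]))
  expect_equal(unname(cv$sigma_y), brute_cov(d$Y, d$Y))
  expect_equal(unname(cv$sigma_y0), brute_cov(d$Y[i0, ], d$Y[i0, ]))
  expect_equal(unname(cv$sigma_y1), brute_cov(d$Y[i1, ], d$Y[i1, ]))

  # pooled standardization makes the pooled covariances correlation matrices
  expect_equal(unname(diag(cv$sigma_x)), rep(1, 2), tolerance = 1e-10)
  expect_equal(unname(diag(cv$sigma_y)), rep(1, 3), tolerance = 1e-10)
  expect_true(isSymmetric(cv$sigma_x) && isSymmetric(cv$sigma_y))

  # single standardized column against itself: variance 1
  d1 <- standardize_columns(
    paired_omics(X[, 1, drop = FALSE], X[, 1, drop = FALSE], z))
  expect_equal(unname(grouped_covariances(d1)$sigma_xy), matrix(1),
               tolerance = 1e-12)
})

test_that("jointly permuting samples leaves every covariance unchanged", {
  set.seed(8)
  d <- standardize_columns(
    paired_omics(matrix(rnorm(40), 10, 4), matrix(rnorm(30), 10, 3),
                 rep(0:1, each = 5)))
  cv <- grouped_covariances(d)
  perm <- sample(10)
  dp <- standardize_columns(
    paired_omics(d$X[perm, ], d$Y[perm, ], d$z[perm]))
  cvp <- grouped_covariances(dp)
  for (nm in names(cv)) {
    expect_equal(unname(cvp[[nm]]), unname(cv[[nm]]), tolerance = 1e-12)
  }
})

test_that("written data round-trips through the loader", {
  dir <- withr::local_tempdir()
  set.seed(9)
  d <- standardize_columns(
    paired_omics(matrix(rnorm(24), 6, 4), matrix(rnorm(18), 6, 3),
                 c(0, 1, 0, 1, 0, 1)))
  paths <- write_paired_data(d, dir)
  d2 <- load_paired_data(paths[1], paths[2], paths[3])
  expect_equal(d2$X, d$X, tolerance = 1e-12)
  expect_equal(d2$Y, d$Y, tolerance = 1e-12)
  expect_equal(d2$z, d$z)
})
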