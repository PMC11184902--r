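#' Construct a paired two-block omics dataset
#'
#' Bundles two sample-by-feature matrices measured on the same samples with a
#' binary group label. This is the input object for screening
#' ([screen_bicliques()]) and model fitting ([fit_dcca()]).
#'
#' @param X Numeric matrix, n samples by p features (e.g. miRNA expression).
#' @param Y Numeric matrix, n samples by q features (e.g. gene expression),
#'   rows aligned with `X`.
#' @param z Binary group label of length n with values 0/1 (e.g. common vs.
#'   rare disease subtype). Both groups must contain at least 2 samples.
#' @param x_names,y_names Optional feature labels; default to the matrix
#'   column names or `X1..Xp` / `Y1..Yq`.
#' @param sample_ids Optional sample labels; default to the row names of `X`
#'   or `S1..Sn`.
#'
#' @return An object of class `paired_omics`: a list with elements `X`, `Y`,
#'   `z`, `x_names`, `y_names`, `sample_ids`.
#'
#' @examples
#' set.seed(1)
#' d <- paired_omics(matrix(rnorm(40), 10, 4), matrix(rnorm(30), 10, 3),
#'                   z = rep(0:1, each = 5))
#' d
#' @export
paired_omics <- function(X, Y, z, x_names = NULL, y_names = NULL,
                         sample_ids = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"

  if (is.factor(z)) z <- as.character(z)
  z <- as.numeric(z)

  n <- nrow(X)
  if (nrow(Y) != n || length(z) != n)
    stop("X, Y and z must have the same number of rows/entries (got ",
         n, ", ", nrow(Y), ", ", length(z), ")")
  if (n < 4L) stop("at least 4 samples are required")
  if (anyNA(X) || anyNA(Y) || anyNA(z))
    stop("missing values are not supported; remove or impute upstream")
  if (!all(z %in% c(0, 1)))
    stop("group label z must be binary 0/1; found values: ",
         paste(unique(z[!z %in% c(0, 1)]), collapse = ", "))
  if (sum(z == 0) < 2L || sum(z == 1) < 2L)
    stop("both groups need at least 2 samples (n0 = ", sum(z == 0),
         ", n1 = ", sum(z == 1), ")")

  x_names <- .feature_names(x_names, colnames(X), ncol(X), "X")
  y_names <- .feature_names(y_names, colnames(Y), ncol(Y), "Y")
  if (anyDuplicated(x_names)) stop("duplicated X feature labels")
  if (anyDuplicated(y_names)) stop("duplicated Y feature labels")
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)

  .check_positive_variance(X, x_names, "X")
  .check_positive_variance(Y, y_names, "Y")

  dimnames(X) <- list(sample_ids, x_names)
  dimnames(Y) <- list(sample_ids, y_names)
  structure(list(X = X, Y = Y, z = z, x_names = x_names, y_names = y_names,
                 sample_ids = sample_ids),
            class = "paired_omics")
}

.feature_names <- function(given, from_matrix, k, prefix) {
  nm <- if (!is.null(given)) given else from_matrix
  if (is.null(nm)) nm <- paste0(prefix, seq_len(k))
  if (length(nm) != k)
    stop("feature label length (", length(nm), ") does not match ", prefix,
         " dimension (", k, ")")
  as.character(nm)
}

.check_positive_variance <- function(M, nms, block) {
  v <- apply(M, 2, stats::var)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad))
    stop("constant (zero-variance) ", block, " column(s): ",
         paste(nms[bad], collapse = ", "))
  invisible(NULL)
}

#' @export
print.paired_omics <- function(x, ...) {
  cat("paired_omics: n =", length(x$z), "samples, p =", ncol(x$X),
      "X features, q =", ncol(x$Y), "Y features\n")
  cat("  groups: n0 =", sum(x$z == 0), ", n1 =", sum(x$z == 1), "\n")
  invisible(x)
}

#' @export
dim.paired_omics <- function(x) {
  c(n = length(x$z), p = ncol(x$X), q = ncol(x$Y))
}

#' Load a paired dataset from delimited text files
#'
#' Reads the two data blocks and the group labels from TSV/CSV files
#' (delimiter auto-detected), aligns all three by sample ID (reordering the
#' Y and group files to the X file's order) and validates the result.
#'
#' @param x_path,y_path Paths to delimited text files with a header row of
#'   feature names and a first column of sample IDs.
#' @param z_path Path to a delimited text file with columns
#'   `sample_id, group` (group coded 0/1).
#' @return A [paired_omics] object.
#' @export
load_paired_data <- function(x_path, y_path, z_path) {
  for (f in c(x_path, y_path, z_path))
    if (!file.exists(f)) stop("file not found: ", f)

  xs <- .read_block(x_path)
  ys <- .read_block(y_path)
  zt <- data.table::fread(z_path, header = TRUE, data.table = FALSE)
  if (ncol(zt) < 2L) stop("group file must have columns sample_id, group")
  z_ids <- as.character(zt[[1L]])

  .check_id_sets(rownames(xs), rownames(ys), "Y")
  .check_id_sets(rownames(xs), z_ids, "group")

  ord_y <- match(rownames(xs), rownames(ys))
  ord_z <- match(rownames(xs), z_ids)
  paired_omics(xs, ys[ord_y, , drop = FALSE], zt[[2L]][ord_z],
               sample_ids = rownames(xs))
}

.read_block <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated sample IDs in ", path)
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric entries in ", path)
  rownames(M) <- ids
  M
}

.check_id_sets <- function(ref, other, label) {
  miss <- setdiff(ref, other)
  extra <- setdiff(other, ref)
  if (length(miss) || length(extra))
    stop("sample IDs of ", label, " file do not match the X file; ",
         if (length(miss)) paste0("missing: ",
                                  paste(utils::head(miss, 5), collapse = ", "), "; "),
         if (length(extra)) paste0("unexpected: ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  invisible(NULL)
}

#' Center and scale the columns of both data blocks
#'
#' Columns are brought to mean 0 and standard deviation 1 (denominator
#' n - 1). The default pooled scope standardizes over all samples jointly, so
#' the pooled cross-covariance becomes a correlation matrix while group-wise
#' covariances keep any between-group mean/scale structure; `per_group`
#' standardizes within each group separately.
#'
#' @param data A [paired_omics] object.
#' @param scope `"pooled"` (default) or `"per_group"`.
#' @return A [paired_omics] object with standardized `X` and `Y`.
#' @export
standardize_columns <- function(data, scope = c("pooled", "per_group")) {
  scope <- match.arg(scope)
  stopifnot(inherits(data, "paired_omics"))
  if (scope == "pooled") {
    data$X <- .scale_block(data$X, data$x_names, "X")
    data$Y <- .scale_block(data$Y, data$y_names, "Y")
  } else {
    for (g in c(0, 1)) {
      idx <- data$z == g
      data$X[idx, ] <- .scale_block(data$X[idx, , drop = FALSE],
                                    data$x_names, paste0("X (group ", g, ")"))
      data$Y[idx, ] <- .scale_block(data$Y[idx, , drop = FALSE],
                                    data$y_names, paste0("Y (group ", g, ")"))
    }
  }
  data
}

.scale_block <- function(M, nms, block) {
  s <- apply(M, 2, stats::sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad))
    stop("zero variance in ", block, " column(s): ",
         paste(nms[bad], collapse = ", "))
  sc <- scale(M, center = TRUE, scale = s)
  attr(sc, "scaled:center") <- NULL
  attr(sc, "scaled:scale") <- NULL
  sc
}

#' Pooled and group-wise (cross-)covariance matrices
#'
#' Computes the nine sample covariance matrices entering the dCCA objective:
#' the pooled and group-wise cross-covariances of (X, Y) and the pooled and
#' group-wise covariances of X and of Y. All use denominator m - 1 where m is
#' the number of rows involved.
#'
#' @param data A [paired_omics] object (typically standardized first; see
#'   [standardize_columns()]).
#' @return An object of class `grouped_covariances`: a list with elements
#'   `sigma_xy`, `sigma_x0y0`, `sigma_x1y1` (p x q), `sigma_x`, `sigma_x0`,
#'   `sigma_x1` (p x p), `sigma_y`, `sigma_y0`, `sigma_y1` (q x q).
#' @export
grouped_covariances <- function(data) {
  stopifnot(inherits(data, "paired_omics"))
  i0 <- data$z == 0
  i1 <- data$z == 1
  if (sum(i0) < 2L || sum(i1) < 2L)
    stop("each group needs at least 2 samples to form covariances")
  X0 <- data$X[i0, , drop = FALSE]; X1 <- data$X[i1, , drop = FALSE]
  Y0 <- data$Y[i0, , drop = FALSE]; Y1 <- data$Y[i1, , drop = FALSE]
  structure(list(
    sigma_xy   = stats::cov(data$X, data$Y),
    sigma_x0y0 = stats::cov(X0, Y0),
    sigma_x1y1 = stats::cov(X1, Y1),
    sigma_x    = stats::cov(data$X),
    sigma_x0   = stats::cov(X0),
    sigma_x1   = stats::cov(X1),
    sigma_y    = stats::cov(data$Y),
    sigma_y0   = stats::cov(Y0),
    sigma_y1   = stats::cov(Y1)),
    class = "grouped_covariances")
}

#' @export
print.grouped_covariances <- function(x, ...) {
  cat("grouped_covariances: p =", nrow(x$sigma_xy),
      ", q =", ncol(x$sigma_xy), "\n")
  invisible(x)
}

#' Restrict a paired dataset to feature subsets
#'
#' @param data A [paired_omics] object.
#' @param x_idx,y_idx Integer indices (or feature names) of the X and Y
#'   columns to keep.
#' @return A [paired_omics] object on the selected features.
#' @export
subset_features <- function(data, x_idx = seq_along(data$x_names),
                            y_idx = seq_along(data$y_names)) {
  stopifnot(inherits(data, "paired_omics"))
  paired_omics(data$X[, x_idx, drop = FALSE], data$Y[, y_idx, drop = FALSE],
               data$z, sample_ids = data$sample_ids)
}

#' Write the two data blocks and group labels back to TSV
#'
#' Companion to [load_paired_data()] for auditing (e.g. after
#' standardization). Files `X.tsv`, `Y.tsv` and `groups.tsv` are written to
#' `dir`.
#'
#' @param data A [paired_omics] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_paired_data <- function(data, dir) {
  stopifnot(inherits(data, "paired_omics"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("X.tsv", "Y.tsv", "groups.tsv"))
  .write_block(data$X, data$sample_ids, paths[1L])
  .write_block(data$Y, data$sample_ids, paths[2L])
  data.table::fwrite(data.frame(sample_id = data$sample_ids, group = data$z),
                     paths[3L], sep = "\t")
  invisible(paths)
}

.write_block <- function(M, ids, path) {
  df <- data.frame(sample_id = ids, M, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
}
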