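#' Edge weights of the bipartite X-Y association graph
#'
#' Builds the p x q weight matrix W of the bipartite graph whose node sets
#' are the X and Y features. The default `"group_max"` weight is the larger
#' of the two within-group absolute Pearson correlations, so feature pairs
#' that are strongly associated in either clinical group produce an edge;
#' this keeps differential pairs visible even when opposite-sign group
#' associations cancel in the pooled correlation. `"pooled"` uses the
#' absolute correlation over all samples.
#'
#' @param data A [paired_omics] object.
#' @param method `"group_max"` (default) or `"pooled"`.
#' @return A p x q matrix with entries in \[0, 1\].
#' @export
edge_weights <- function(data, method = c("group_max", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "paired_omics"))
  W <- if (method == "pooled") {
    abs(stats::cor(data$X, data$Y))
  } else {
    i0 <- data$z == 0
    pmax(abs(stats::cor(data$X[i0, , drop = FALSE], data$Y[i0, , drop = FALSE])),
         abs(stats::cor(data$X[!i0, , drop = FALSE], data$Y[!i0, , drop = FALSE])))
  }
  dimnames(W) <- list(data$x_names, data$y_names)
  W
}

#' Threshold edge weights into a biadjacency matrix
#'
#' @param W Non-negative weight matrix (see [edge_weights()]).
#' @param r Threshold in \[0, 1); an edge is kept iff its weight is strictly
#'   greater than `r`.
#' @return A binary matrix of the same shape as `W`.
#' @export
binarize <- function(W, r) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1)
    stop("threshold r must be a single value in [0, 1)")
  A <- (W > r) + 0
  dimnames(A) <- dimnames(W)
  A
}

#' Quasi-biclique density objective
#'
#' The score of a candidate biclique (nx, ny): the number of edges inside the
#' induced sub-block divided by its area raised to the density exponent
#' `lambda_k`. `lambda_k = 1` scores pure density; values below 1 reward
#' larger blocks, values above 1 reward smaller, denser blocks.
#'
#' @param A Binary biadjacency matrix.
#' @param nx,ny Non-empty integer index sets on the rows/columns of `A`.
#' @param lambda_k Positive density exponent.
#' @return The objective value (a single number).
#' @export
biclique_objective <- function(A, nx, ny, lambda_k) {
  if (length(nx) == 0L || length(ny) == 0L)
    stop("biclique node sets must be non-empty")
  if (!is.numeric(lambda_k) || lambda_k <= 0)
    stop("lambda_k must be positive")
  sum(A[nx, ny]) / (length(nx) * length(ny))^lambda_k
}

#' Greedy extraction of one quasi-biclique
#'
#' Local search for a dense sub-block of the biadjacency matrix: start from
#' the admissible edge whose endpoints have the largest combined degree
#' (breaking ties by edge weight when `W` is supplied, then by lowest
#' index), then repeatedly apply the best single-node addition or removal
#' on either side while the quasi-biclique objective strictly increases.
#' Degree-based seeding places the start inside the densest region, so
#' sequential extraction finds large dense blocks before small ones.
#' Deterministic: move ties are broken by move type (additions before
#' removals, X side before Y side) and then by lowest feature index.
#'
#' @param A Binary biadjacency matrix.
#' @param excluded_x,excluded_y Row/column indices that may not be used
#'   (already claimed by previously extracted bicliques).
#' @param lambda_k Positive density exponent of the objective.
#' @param W Optional weight matrix used only to pick the seed edge.
#' @return An object of class `quasi_biclique` (fields `nx`, `ny`,
#'   `lambda_k`, `n_edges`, `density`, `objective`), or `NULL` when no
#'   admissible edge exists.
#' @export
greedy_quasi_biclique <- function(A, excluded_x = integer(0),
                                  excluded_y = integer(0), lambda_k = 1,
                                  W = NULL) {
  if (!is.numeric(lambda_k) || lambda_k <= 0) stop("lambda_k must be positive")
  p <- nrow(A); q <- ncol(A)
  adm_x <- setdiff(seq_len(p), excluded_x)
  adm_y <- setdiff(seq_len(q), excluded_y)
  if (!length(adm_x) || !length(adm_y)) return(NULL)

  sub <- A[adm_x, adm_y, drop = FALSE]
  if (sum(sub) == 0) return(NULL)

  # seed at the edge with maximal combined endpoint degree; ties broken by
  # weight (when given), then by lowest index
  deg <- outer(rowSums(sub), colSums(sub), "+") * sub
  seed_score <- deg
  if (!is.null(W))
    seed_score <- deg + W[adm_x, adm_y, drop = FALSE] * sub /
      (max(W) + 1)                      # weight term < 1 degree unit
  k <- which.max(seed_score)
  i0 <- adm_x[(k - 1L) %% length(adm_x) + 1L]
  j0 <- adm_y[(k - 1L) %/% length(adm_x) + 1L]

  in_x <- logical(p); in_y <- logical(q)
  in_x[i0] <- TRUE; in_y[j0] <- TRUE
  ok_x <- logical(p); ok_y <- logical(q)
  ok_x[adm_x] <- TRUE; ok_y[adm_y] <- TRUE
  rs <- A[, j0]              # ones of each row within current ny
  cs <- A[i0, ]              # ones of each column within current nx
  ones <- A[i0, j0]
  nx <- 1L; ny <- 1L
  obj <- ones / (nx * ny)^lambda_k

  repeat {
    best_val <- -Inf; best_move <- NULL

    cand <- which(ok_x & !in_x)
    if (length(cand)) {
      vals <- (ones + rs[cand]) / ((nx + 1L) * ny)^lambda_k
      m <- which.max(vals)
      if (vals[m] > best_val) { best_val <- vals[m]; best_move <- c(1L, cand[m]) }
    }
    cand <- which(ok_y & !in_y)
    if (length(cand)) {
      vals <- (ones + cs[cand]) / (nx * (ny + 1L))^lambda_k
      m <- which.max(vals)
      if (vals[m] > best_val) { best_val <- vals[m]; best_move <- c(2L, cand[m]) }
    }
    if (nx > 1L) {
      cand <- which(in_x)
      vals <- (ones - rs[cand]) / ((nx - 1L) * ny)^lambda_k
      m <- which.max(vals)
      if (vals[m] > best_val) { best_val <- vals[m]; best_move <- c(3L, cand[m]) }
    }
    if (ny > 1L) {
      cand <- which(in_y)
      vals <- (ones - cs[cand]) / (nx * (ny - 1L))^lambda_k
      m <- which.max(vals)
      if (vals[m] > best_val) { best_val <- vals[m]; best_move <- c(4L, cand[m]) }
    }

    if (!is.finite(best_val) || best_val <= obj * (1 + 1e-12)) break
    type <- best_move[1L]; idx <- best_move[2L]
    if (type == 1L) {        # add x
      ones <- ones + rs[idx]; cs <- cs + A[idx, ]; in_x[idx] <- TRUE; nx <- nx + 1L
    } else if (type == 2L) { # add y
      ones <- ones + cs[idx]; rs <- rs + A[, idx]; in_y[idx] <- TRUE; ny <- ny + 1L
    } else if (type == 3L) { # remove x
      ones <- ones - rs[idx]; cs <- cs - A[idx, ]; in_x[idx] <- FALSE; nx <- nx - 1L
    } else {                 # remove y
      ones <- ones - cs[idx]; rs <- rs - A[, idx]; in_y[idx] <- FALSE; ny <- ny - 1L
    }
    obj <- best_val
  }

  nxs <- which(in_x); nys <- which(in_y)
  structure(list(nx = nxs, ny = nys, lambda_k = lambda_k,
                 n_edges = ones, density = ones / (nx * ny),
                 objective = obj),
            class = "quasi_biclique")
}

#' @export
print.quasi_biclique <- function(x, ...) {
  cat("quasi_biclique: ", length(x$nx), " x ", length(x$ny),
      " block, density ", signif(x$density, 3),
      ", objective ", signif(x$objective, 4),
      " (lambda_k = ", x$lambda_k, ")\n", sep = "")
  invisible(x)
}

#' Bernoulli-mixture fit of a biadjacency matrix around a block
#'
#' Under the mixture model, edges inside the candidate block are
#' Bernoulli(pi1) and edges outside are Bernoulli(pi0); the reference model
#' is a single Bernoulli(pi) with no block structure. The maximum-likelihood
#' estimates are the corresponding sample proportions; the KL divergence
#' between mixture and reference (see [kl_divergence()]) measures how much
#' block structure the data support.
#'
#' @param A Binary biadjacency matrix (restricted to the admissible region
#'   when previous bicliques have been carved out).
#' @param nx,ny Row/column index sets of the candidate block.
#' @return An object of class `bernoulli_mixture_fit` with fields `pi`,
#'   `pi0`, `pi1`, `kl`.
#' @export
bernoulli_mle <- function(A, nx, ny) {
  if (length(nx) == 0L || length(ny) == 0L)
    stop("block index sets must be non-empty")
  n_in <- length(nx) * length(ny)
  n_out <- length(A) - n_in
  if (n_out <= 0L) stop("no cells outside the block; cannot fit the mixture")
  ones_in <- sum(A[nx, ny])
  fit <- structure(list(pi = sum(A) / length(A),
                        pi1 = ones_in / n_in,
                        pi0 = (sum(A) - ones_in) / n_out,
                        kl = NA_real_),
                   class = "bernoulli_mixture_fit")
  fit$kl <- kl_divergence(fit, A, nx, ny)
  fit
}

#' KL divergence of the Bernoulli mixture against the no-block reference
#'
#' Evaluates, with natural logarithms, the cell-wise sum of
#' `A_ij * pi1 * log(pi1/pi) + (1 - A_ij) * (1 - pi1) * log((1-pi1)/(1-pi))`
#' over in-block cells plus the `pi0` analogue over out-of-block cells.
#' Probabilities are clipped to \[1e-6, 1 - 1e-6\] so perfectly dense or
#' empty regions do not produce log(0).
#'
#' @param fit A `bernoulli_mixture_fit` (the `kl` field is ignored).
#' @param A Binary biadjacency matrix.
#' @param nx,ny Row/column index sets of the block.
#' @return The divergence (a single number; 0 when `pi1 == pi0 == pi`).
#' @export
kl_divergence <- function(fit, A, nx, ny) {
  eps <- 1e-6
  pi_ <- min(max(fit$pi, eps), 1 - eps)
  pi1 <- min(max(fit$pi1, eps), 1 - eps)
  pi0 <- min(max(fit$pi0, eps), 1 - eps)

  n_in <- length(nx) * length(ny)
  ones_in <- sum(A[nx, ny])
  zeros_in <- n_in - ones_in
  ones_out <- sum(A) - ones_in
  zeros_out <- length(A) - n_in - ones_out

  kl <- ones_in * pi1 * log(pi1 / pi_) +
    zeros_in * (1 - pi1) * log((1 - pi1) / (1 - pi_)) +
    ones_out * pi0 * log(pi0 / pi_) +
    zeros_out * (1 - pi0) * log((1 - pi0) / (1 - pi_))
  if (kl < 0 && kl > -1e-12) kl <- 0
  kl
}

#' Select the density exponent of one biclique by KL divergence
#'
#' Runs the greedy extractor for every exponent in `grid`, scores each
#' resulting block by the Bernoulli-mixture KL divergence over the
#' admissible region, and returns the exponent with the largest divergence
#' (ties broken toward the larger, more parsimonious exponent).
#'
#' @param A Binary biadjacency matrix.
#' @param excluded_x,excluded_y Indices claimed by earlier bicliques.
#' @param grid Non-empty vector of positive exponents.
#' @param W Optional weights for greedy seeding.
#' @return `NULL` when no admissible edge remains; otherwise a list with
#'   `lambda_k`, `biclique`, `fit` (the mixture fit), and `kl_by_lambda`.
#' @export
select_lambda_k <- function(A, excluded_x = integer(0),
                            excluded_y = integer(0),
                            grid = seq(0.5, 1.5, by = 0.1), W = NULL) {
  if (!length(grid)) stop("lambda grid must be non-empty")
  adm_x <- setdiff(seq_len(nrow(A)), excluded_x)
  adm_y <- setdiff(seq_len(ncol(A)), excluded_y)
  A_adm <- A[adm_x, adm_y, drop = FALSE]

  kls <- rep(NA_real_, length(grid))
  best <- NULL
  for (g in seq_along(grid)) {
    bc <- greedy_quasi_biclique(A, excluded_x, excluded_y, grid[g], W = W)
    if (is.null(bc)) return(NULL)
    fit <- tryCatch(
      bernoulli_mle(A_adm, match(bc$nx, adm_x), match(bc$ny, adm_y)),
      error = function(e) NULL)
    if (is.null(fit)) next
    kls[g] <- fit$kl
    if (is.null(best) || fit$kl >= best$kl - 1e-12)   # >= prefers larger lambda
      best <- list(lambda_k = grid[g], biclique = bc, fit = fit, kl = fit$kl)
  }
  if (is.null(best)) return(NULL)
  best$kl_by_lambda <- stats::setNames(kls, grid)
  best
}

#' Quasi-biclique screening of a paired dataset
#'
#' Reduces dimensionality before dCCA fitting: builds the thresholded
#' bipartite association graph between the X and Y features, then extracts
#' up to `max_blocks` dense quasi-bicliques sequentially, each side-disjoint
#' from the previous ones, with the density exponent of each block tuned by
#' KL divergence. Extraction stops early when a new block carries
#' negligible information: when its KL divergence drops below 5% of the
#' largest KL among the blocks extracted so far, when its density falls
#' below twice the overall edge density (no real enrichment), when it is
#' thinner than 2 features on either side (a width-1 block is a star, not
#' a dense biclique), or when no admissible edges remain. Features outside
#' every block are screened out.
#'
#' @param data A [paired_omics] object.
#' @param r Edge threshold in \[0, 1); the default is the critical value of
#'   a two-sided Fisher-z correlation test at per-edge level
#'   `edge_level`, computed from the smaller group size for `"group_max"`
#'   weights (the full sample size for `"pooled"`), so the null edge
#'   density adapts to the sample size instead of being a fixed fraction
#'   of all feature pairs.
#' @param edge_level Per-edge two-sided significance level behind the
#'   default threshold (default 0.005).
#' @param max_blocks Maximum number of bicliques to extract (default 3).
#' @param lambda_grid Candidate density exponents (default 0.5 to 1.5 by 0.1).
#' @param weight Edge weight type, see [edge_weights()].
#' @return An object of class `bipartite_screen` with fields `W`, `r`, `A`,
#'   `bicliques` (list of `quasi_biclique`, in extraction order),
#'   `retained_x`, `retained_y` (index unions), `kl` (per block). Zero
#'   bicliques is a legal outcome; callers then fit dCCA unscreened.
#' @seealso [fit_all_blocks()], [screen_table()]
#' @export
screen_bicliques <- function(data, r = NULL, max_blocks = 3,
                             lambda_grid = seq(0.5, 1.5, by = 0.1),
                             weight = c("group_max", "pooled"),
                             edge_level = 0.005) {
  stopifnot(inherits(data, "paired_omics"))
  if (max_blocks < 0) stop("max_blocks must be >= 0")
  weight <- match.arg(weight)
  W <- edge_weights(data, method = weight)
  if (is.null(r)) {
    m <- if (weight == "group_max")
      min(sum(data$z == 0), sum(data$z == 1)) else length(data$z)
    r <- tanh(stats::qnorm(1 - edge_level / 2) / sqrt(m - 3))
  }
  if (r >= 1) r <- 1 - 1e-8
  A <- binarize(W, r)

  bicliques <- list()
  kls <- numeric(0)
  exc_x <- integer(0); exc_y <- integer(0)
  kl_max <- -Inf

  while (length(bicliques) < max_blocks) {
    res <- select_lambda_k(A, exc_x, exc_y, grid = lambda_grid, W = W)
    if (is.null(res)) break
    bc <- res$biclique
    degenerate <- length(bc$nx) < 2L || length(bc$ny) < 2L
    not_enriched <- bc$density < 2 * res$fit$pi
    negligible <- is.finite(kl_max) && res$kl < 0.05 * kl_max
    if (degenerate || not_enriched || negligible) break
    bicliques[[length(bicliques) + 1L]] <- bc
    kls <- c(kls, res$kl)
    kl_max <- max(kl_max, res$kl)
    exc_x <- c(exc_x, bc$nx)
    exc_y <- c(exc_y, bc$ny)
  }

  structure(list(W = W, r = r, A = A, bicliques = bicliques, kl = kls,
                 retained_x = sort(unique(unlist(lapply(bicliques, `[[`, "nx")))),
                 retained_y = sort(unique(unlist(lapply(bicliques, `[[`, "ny")))),
                 x_names = data$x_names, y_names = data$y_names),
            class = "bipartite_screen")
}

#' @export
print.bipartite_screen <- function(x, ...) {
  cat("bipartite_screen: threshold r =", signif(x$r, 3), "\n")
  cat("  ", length(x$bicliques), "biclique(s);",
      length(x$retained_x), "of", nrow(x$W), "X features and",
      length(x$retained_y), "of", ncol(x$W), "Y features retained\n")
  for (k in seq_along(x$bicliques)) {
    b <- x$bicliques[[k]]
    cat(sprintf("  block %d: %d x %d, density %.3f, lambda_k %.2f, KL %.1f\n",
                k, length(b$nx), length(b$ny), b$density, b$lambda_k, x$kl[k]))
  }
  invisible(x)
}

#' Tabulate screening results
#'
#' @param screen A `bipartite_screen` object.
#' @return A data frame with one row per retained feature: `feature`,
#'   `block` (side = "X"/"Y", block id in extraction order).
#' @export
screen_table <- function(screen) {
  stopifnot(inherits(screen, "bipartite_screen"))
  rows <- list()
  for (k in seq_along(screen$bicliques)) {
    b <- screen$bicliques[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = c(screen$x_names[b$nx], screen$y_names[b$ny]),
      side = rep(c("X", "Y"), c(length(b$nx), length(b$ny))),
      block = k)
  }
  if (!length(rows))
    return(data.frame(feature = character(0), side = character(0),
                      block = integer(0)))
  do.call(rbind, rows)
}

#' Edge list of the screened graph
#'
#' @param screen A `bipartite_screen` object.
#' @return A data frame with columns `x_feature`, `y_feature`, `weight`,
#'   `block` for every retained edge (A = 1) inside a biclique; suitable for
#'   graph tools.
#' @export
screen_edge_list <- function(screen) {
  stopifnot(inherits(screen, "bipartite_screen"))
  rows <- list()
  for (k in seq_along(screen$bicliques)) {
    b <- screen$bicliques[[k]]
    sub <- screen$A[b$nx, b$ny, drop = FALSE]
    idx <- which(sub == 1, arr.ind = TRUE)
    if (nrow(idx))
      rows[[length(rows) + 1L]] <- data.frame(
        x_feature = screen$x_names[b$nx[idx[, 1L]]],
        y_feature = screen$y_names[b$ny[idx[, 2L]]],
        weight = screen$W[cbind(b$nx[idx[, 1L]], b$ny[idx[, 2L]])],
        block = k)
  }
  if (!length(rows))
    return(data.frame(x_feature = character(0), y_feature = character(0),
                      weight = numeric(0), block = integer(0)))
  do.call(rbind, rows)
}
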