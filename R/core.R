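#' Evaluate the relaxed dCCA objective
#'
#' The criterion maximized by [fit_dcca()] under unit-norm loadings:
#' `u' S_XY v + lambda * | u' (S_X0Y0 - S_X1Y1) v |`, where `S_XY` is the
#' pooled cross-covariance and the second term is the absolute between-group
#' cross-covariance discrepancy along (u, v).
#'
#' @param u,v Loading vectors of length p and q.
#' @param cov A [grouped_covariances] object.
#' @param lam Non-negative tuning parameter balancing the pooled association
#'   against the between-group discrepancy.
#' @return The objective value.
#' @export
dcca_objective <- function(u, v, cov, lam) {
  stopifnot(inherits(cov, "grouped_covariances"), lam >= 0)
  if (length(u) != nrow(cov$sigma_xy) || length(v) != ncol(cov$sigma_xy))
    stop("loading vector lengths (", length(u), ", ", length(v),
         ") do not match the covariance dimensions (",
         nrow(cov$sigma_xy), ", ", ncol(cov$sigma_xy), ")")
  drop(crossprod(u, cov$sigma_xy %*% v)) +
    lam * abs(drop(crossprod(u, (cov$sigma_x0y0 - cov$sigma_x1y1) %*% v)))
}

#' Fit differential canonical correlation loadings
#'
#' Maximizes [dcca_objective()] over unit-norm u and v. The absolute-value
#' discrepancy term splits the problem into two smooth branches, one per
#' sign s of `u'(S_X0Y0 - S_X1Y1)v`; each branch is the operator-norm
#' problem of the sign-adjusted matrix `M_s = S_XY + s * lambda * (S_X0Y0 -
#' S_X1Y1)` and is solved by singular-vector (power) iteration from the
#' leading singular pair, with the normalization constants of each update
#' playing the role of the Lagrange multipliers of the two unit-norm
#' constraints. Both branches are optimized to convergence and the one with
#' the larger objective wins. Columns are standardized (pooled) internally,
#' so the fit is invariant to the units of individual features.
#'
#' The returned loadings follow the sign convention `rho0 >= rho1` (flipping
#' u alone negates all three canonical correlations and is used to enforce
#' it; flipping u and v jointly changes nothing).
#'
#' @param data A [paired_omics] object.
#' @param lam Non-negative tuning parameter (see [select_lambda_cv()]).
#' @param max_iter Maximum power-iteration sweeps per branch (default 500).
#' @param tol Relative objective-change convergence tolerance (default 1e-8).
#' @param init `"svd"` (default: leading singular pair of `M_s`) or
#'   `"random"` (seeded random start, mainly for diagnostics).
#' @param block_id Optional integer recorded in the solution (used by
#'   [fit_all_blocks()]).
#' @return An object of class `dcca_solution`: unit-norm loadings `u`, `v`
#'   (named by feature), `lam`, canonical correlations `rho_pooled`, `rho0`,
#'   `rho1`, the converged `objective`, `n_iter`, `converged`, `block_id`,
#'   and a `trace` list (objective history, final normalization constants
#'   `alpha`/`beta`, active `sign_branch`, objective of the discarded
#'   branch).
#' @export
fit_dcca <- function(data, lam = 0, max_iter = 500, tol = 1e-8,
                     init = c("svd", "random"), block_id = NA_integer_) {
  stopifnot(inherits(data, "paired_omics"), lam >= 0)
  init <- match.arg(init)
  data <- standardize_columns(data, "pooled")
  cov <- grouped_covariances(data)
  delta <- cov$sigma_x0y0 - cov$sigma_x1y1

  branches <- if (lam == 0) 1 else c(1, -1)
  fits <- lapply(branches, function(s)
    .power_branch(cov$sigma_xy + s * lam * delta, max_iter, tol, init))
  objs <- vapply(fits, function(f)
    dcca_objective(f$u, f$v, cov, lam), numeric(1))
  best <- which.max(objs)
  f <- fits[[best]]
  if (anyNA(f$u) || anyNA(f$v)) stop("NaN encountered in the dCCA updates")
  if (!f$converged)
    warning("dCCA did not converge in ", max_iter, " sweeps")

  u <- f$u; v <- f$v
  rho <- .projection_correlations(data, u, v)
  if (rho$rho0 < rho$rho1) {      # sign convention: rho0 >= rho1
    u <- -u
    rho <- lapply(rho, function(r) -r)
  }
  names(u) <- data$x_names
  names(v) <- data$y_names

  structure(list(
    u = u, v = v, lam = lam,
    rho_pooled = rho$rho_pooled, rho0 = rho$rho0, rho1 = rho$rho1,
    objective = objs[best], n_iter = f$n_iter, converged = f$converged,
    block_id = block_id,
    x_names = data$x_names, y_names = data$y_names,
    trace = list(objective_history = f$history,
                 alpha = f$alpha, beta = f$beta,
                 sign_branch = branches[best],
                 step_count = f$n_iter,
                 objective_other_branch =
                   if (length(objs) > 1) objs[-best] else NA_real_)),
    class = "dcca_solution")
}

# Power iteration for the leading singular pair of M; at the fixed point
# u = M v / alpha and v = M' u / beta, matching stationarity of the
# Lagrangian of the unit-norm constrained bilinear maximization.
.power_branch <- function(M, max_iter, tol, init) {
  sv <- svd(M, nu = 1, nv = 1)
  if (init == "svd") {
    u <- sv$u[, 1L]; v <- sv$v[, 1L]
  } else {
    u <- stats::rnorm(nrow(M)); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(ncol(M)); v <- v / sqrt(sum(v^2))
  }
  obj <- drop(crossprod(u, M %*% v))
  history <- obj
  alpha <- beta <- NA_real_
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mu <- M %*% v
    alpha <- sqrt(sum(Mu^2))
    if (alpha == 0) break
    u <- drop(Mu) / alpha
    Mv <- crossprod(M, u)
    beta <- sqrt(sum(Mv^2))
    if (beta == 0) break
    v <- drop(Mv) / beta
    new_obj <- drop(crossprod(u, M %*% v))
    history <- c(history, new_obj)
    if (abs(new_obj - obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  list(u = u, v = v, n_iter = it, converged = converged || alpha == 0,
       history = history, alpha = alpha, beta = beta)
}

.projection_correlations <- function(data, u, v) {
  su <- drop(data$X %*% u)
  sv <- drop(data$Y %*% v)
  i0 <- data$z == 0
  .safe_cor <- function(a, b, label) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance projection in ", label,
           "; canonical correlation undefined")
    stats::cor(a, b)
  }
  list(rho_pooled = .safe_cor(su, sv, "the pooled sample"),
       rho0 = .safe_cor(su[i0], sv[i0], "group 0"),
       rho1 = .safe_cor(su[!i0], sv[!i0], "group 1"))
}

#' @export
print.dcca_solution <- function(x, ...) {
  cat("dcca_solution (lambda =", x$lam,
      if (!is.na(x$block_id)) paste0(", block ", x$block_id), ")\n")
  cat(sprintf("  rho_pooled = %.4f, rho0 = %.4f, rho1 = %.4f\n",
              x$rho_pooled, x$rho0, x$rho1))
  cat(sprintf("  objective = %.6f after %d sweep(s)%s\n", x$objective,
              x$n_iter, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Fit dCCA separately on each screened biclique
#'
#' @param data The full [paired_omics] object.
#' @param screen A `bipartite_screen` from [screen_bicliques()].
#' @param lam Non-negative tuning parameter applied to every block.
#' @param ... Passed to [fit_dcca()] (`max_iter`, `tol`, `init`).
#' @return A list of `dcca_solution` objects, one per biclique of at least
#'   2 x 2 features (smaller blocks are skipped with a warning), each with
#'   `block_id` set and full-length embedded loadings in `u_full`, `v_full`
#'   (zeros outside the block).
#' @export
fit_all_blocks <- function(data, screen, lam = 0, ...) {
  stopifnot(inherits(data, "paired_omics"),
            inherits(screen, "bipartite_screen"))
  if (!length(screen$bicliques)) stop("screen contains no bicliques")
  out <- list()
  for (k in seq_along(screen$bicliques)) {
    b <- screen$bicliques[[k]]
    if (length(b$nx) < 2L || length(b$ny) < 2L) {
      warning("block ", k, " is smaller than 2 x 2; skipped")
      next
    }
    sol <- fit_dcca(subset_features(data, b$nx, b$ny), lam = lam,
                    block_id = k, ...)
    u_full <- stats::setNames(numeric(ncol(data$X)), data$x_names)
    v_full <- stats::setNames(numeric(ncol(data$Y)), data$y_names)
    u_full[b$nx] <- sol$u
    v_full[b$ny] <- sol$v
    sol$u_full <- u_full
    sol$v_full <- v_full
    out[[length(out) + 1L]] <- sol
  }
  out
}

#' Choose the dCCA tuning parameter by stratified cross-validation
#'
#' Folds are stratified by group so both groups appear in every training and
#' validation split. For each candidate lambda the model is fitted on the
#' training folds and scored on the held-out fold with the
#' lambda-independent criterion
#' `|Cor(Xu, Yv)| + |Cor(X0 u, Y0 v) - Cor(X1 u, Y1 v)|`
#' computed on validation samples; correlations rather than covariances make
#' scores comparable across lambda and prevent trivially selecting the
#' largest value, and the absolute value on the pooled term makes the score
#' invariant to the sign indeterminacy of the loadings.
#' By default the smallest lambda whose mean score lies within one standard
#' error of the best is selected (the usual one-SE parsimony rule):
#' engaging the discrepancy term requires the held-out data to genuinely
#' support it, which keeps a no-difference dataset from being fitted with a
#' positive lambda on the strength of cross-validation noise. With
#' `one_se = FALSE` the plain maximizer wins (ties toward the smaller
#' lambda).
#'
#' @param data A [paired_omics] object.
#' @param grid Non-negative candidate values (default 0, 0.25, 0.5, 1, 2, 4).
#' @param folds Number of folds (default 5); each group must contribute at
#'   least 2 samples to every fold.
#' @param seed Integer seed controlling fold assignment.
#' @param one_se Apply the one-standard-error rule (default `TRUE`).
#' @param ... Passed to [fit_dcca()].
#' @return A list with `lambda` (the selected value), `mean_scores` (named
#'   by lambda) and `fold_scores` (lambda x fold matrix).
#' @export
select_lambda_cv <- function(data, grid = c(0, 0.25, 0.5, 1, 2, 4),
                             folds = 5, seed = 1, one_se = TRUE, ...) {
  stopifnot(inherits(data, "paired_omics"), folds >= 2, length(grid) >= 1)
  z <- data$z
  fold_id <- integer(length(z))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (g in c(0, 1)) {
    idx <- which(z == g)
    if (length(idx) < 2 * folds)
      stop("group ", g, " has too few samples (", length(idx),
           ") for ", folds, "-fold stratified CV; reduce folds")
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  scores <- matrix(NA_real_, length(grid), folds,
                   dimnames = list(grid, NULL))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    train <- paired_omics(data$X[tr, , drop = FALSE],
                          data$Y[tr, , drop = FALSE], z[tr])
    val <- list(X = data$X[!tr, , drop = FALSE],
                Y = data$Y[!tr, , drop = FALSE], z = z[!tr])
    for (g in seq_along(grid)) {
      sol <- fit_dcca(train, lam = grid[g], ...)
      scores[g, f] <- .validation_score(val, sol$u, sol$v)
    }
  }
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  best <- which.max(mean_scores)           # first max: ties -> smaller lambda
  if (one_se) {
    se_best <- stats::sd(scores[best, ]) / sqrt(sum(is.finite(scores[best, ])))
    if (is.finite(se_best)) {
      cand <- which(mean_scores >= mean_scores[best] - se_best)
      best <- cand[which.min(grid[cand])]
    }
  }
  list(lambda = grid[best], mean_scores = mean_scores, fold_scores = scores)
}

.validation_score <- function(val, u, v) {
  su <- drop(val$X %*% u)
  sv <- drop(val$Y %*% v)
  i0 <- val$z == 0
  cor_or_na <- function(a, b)
    if (length(a) >= 2 && stats::sd(a) > 0 && stats::sd(b) > 0)
      stats::cor(a, b) else NA_real_
  pooled <- cor_or_na(su, sv)
  c0 <- cor_or_na(su[i0], sv[i0])
  c1 <- cor_or_na(su[!i0], sv[!i0])
  if (is.na(pooled) || is.na(c0) || is.na(c1)) return(NA_real_)
  abs(pooled) + abs(c0 - c1)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
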