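#' Canonical correlations of a fitted solution on a dataset
#'
#' Projects the data onto the fitted loadings and returns the Pearson
#' correlations of the canonical variables within each group and pooled.
#'
#' @param solution A `dcca_solution` (see [fit_dcca()]).
#' @param data A [paired_omics] object on the same feature space as the
#'   solution (or the full space when the solution carries embedded
#'   `u_full`/`v_full` loadings).
#' @return A list with `rho0`, `rho1`, `rho_pooled`.
#' @export
group_correlations <- function(solution, data) {
  stopifnot(inherits(solution, "dcca_solution"),
            inherits(data, "paired_omics"))
  u <- solution$u; v <- solution$v
  if (length(u) != ncol(data$X) || length(v) != ncol(data$Y)) {
    if (!is.null(solution$u_full) &&
        length(solution$u_full) == ncol(data$X) &&
        length(solution$v_full) == ncol(data$Y)) {
      u <- solution$u_full; v <- solution$v_full
    } else {
      stop("solution loadings do not match the data dimensions")
    }
  }
  r <- .projection_correlations(data, u, v)
  list(rho0 = r$rho0, rho1 = r$rho1, rho_pooled = r$rho_pooled)
}

#' Test the difference of two independent canonical correlations
#'
#' Two-sample Fisher-z test: both correlations are variance-stabilized with
#' atanh, and the standardized difference
#' `z = (atanh(rho0) - atanh(rho1)) / sqrt(1/(n0-3) + 1/(n1-3))`
#' is referred to the standard normal (two-sided). This is the standard test
#' for a difference of correlations estimated on disjoint subject sets.
#'
#' @param rho0_hat,rho1_hat Estimated canonical correlations per group.
#'   Values of exactly +/-1 are clipped to +/-(1 - 1e-12) with a warning.
#' @param n0,n1 Group sizes (each at least 4).
#' @param alpha Test level (default 0.05).
#' @return An object of class `dcca_diff_test` with fields `rho0_hat`,
#'   `rho1_hat`, `n0`, `n1`, `z_stat`, `p_value`, `alpha`, `reject`.
#' @export
test_difference <- function(rho0_hat, rho1_hat, n0, n1, alpha = 0.05) {
  stopifnot(n0 >= 4, n1 >= 4, alpha > 0, alpha < 1,
            abs(rho0_hat) <= 1, abs(rho1_hat) <= 1)
  clip <- function(r) {
    if (abs(r) >= 1) {
      warning("correlation of ", r, " clipped to +/-(1 - 1e-12)")
      sign(r) * (1 - 1e-12)
    } else r
  }
  r0 <- clip(rho0_hat); r1 <- clip(rho1_hat)
  z <- (atanh(r0) - atanh(r1)) / sqrt(1 / (n0 - 3) + 1 / (n1 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(rho0_hat = rho0_hat, rho1_hat = rho1_hat, n0 = n0, n1 = n1,
                 z_stat = z, p_value = p, alpha = alpha,
                 reject = p < alpha),
            class = "dcca_diff_test")
}

#' @export
print.dcca_diff_test <- function(x, ...) {
  cat("Fisher-z test for a difference of canonical correlations\n")
  cat(sprintf("  rho0 = %.4f (n0 = %d), rho1 = %.4f (n1 = %d)\n",
              x$rho0_hat, x$n0, x$rho1_hat, x$n1))
  cat(sprintf("  z = %.3f, p = %.4g -> %s at alpha = %g\n", x$z_stat,
              x$p_value, if (x$reject) "reject" else "do not reject",
              x$alpha))
  invisible(x)
}

#' Group-classification AUC from canonical variables
#'
#' Builds, for every fitted block, the canonical variables `Xu_k`, `Yv_k`
#' and their product `(Xu_k)(Yv_k)`, fits a logistic regression of the group
#' label on these scores, and returns the ROC AUC of the fitted
#' probabilities (orientation-corrected to be at least 0.5). The product
#' term carries the group information when the two groups differ in the
#' *correlation* of the canonical variables rather than in their means, the
#' situation dCCA targets. In-sample by default; `cv_folds > 0` gives a
#' stratified cross-validated AUC instead.
#'
#' @param solutions A `dcca_solution` or a list of them (e.g. from
#'   [fit_all_blocks()]).
#' @param data The [paired_omics] object the solutions were fitted to.
#' @param seed Integer seed (used only for the cross-validated variant).
#' @param cv_folds 0 (default, in-sample) or the number of CV folds.
#' @return The AUC (single number in \[0.5, 1\]); attribute `"note"` records
#'   perfect separation when it occurs.
#' @export
classification_auc <- function(solutions, data, seed = 1, cv_folds = 0) {
  stopifnot(inherits(data, "paired_omics"))
  if (inherits(solutions, "dcca_solution")) solutions <- list(solutions)
  if (!length(solutions)) stop("at least one solution is required")

  S <- do.call(cbind, lapply(solutions, function(sol) {
    u <- sol$u; v <- sol$v
    if (length(u) != ncol(data$X)) { u <- sol$u_full; v <- sol$v_full }
    su <- drop(data$X %*% u)
    sv <- drop(data$Y %*% v)
    cbind(su, sv, su * sv)
  }))
  z <- data$z
  df <- data.frame(z = z, S)

  note <- NULL
  fit_prob <- function(train_df, newdata) {
    fit <- withCallingHandlers(
      stats::glm(z ~ ., data = train_df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          note <<- "perfect separation"
        invokeRestart("muffleWarning")
      })
    stats::predict(fit, newdata = newdata, type = "response")
  }

  if (cv_folds > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fold_id <- integer(length(z))
    for (g in c(0, 1)) {
      idx <- which(z == g)
      fold_id[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    prob <- numeric(length(z))
    for (f in seq_len(cv_folds)) {
      tr <- fold_id != f
      prob[!tr] <- fit_prob(df[tr, , drop = FALSE], df[!tr, , drop = FALSE])
    }
  } else {
    prob <- fit_prob(df, df)
  }

  if (length(unique(prob)) == 1L) {
    auc <- 0.5
  } else {
    roc <- pROC::roc(response = z, predictor = prob, levels = c(0, 1),
                     direction = "<", quiet = TRUE)
    auc <- max(as.numeric(pROC::auc(roc)), 1 - as.numeric(pROC::auc(roc)))
  }
  if (!is.null(note)) attr(auc, "note") <- note
  auc
}

#' Serialize a difference test to JSON and TSV
#'
#' @param test A `dcca_diff_test`.
#' @param json_path,tsv_path Optional output paths; either may be `NULL`.
#' @return Invisibly, the one-row data frame written to TSV.
#' @export
write_diff_test <- function(test, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(test, "dcca_diff_test"))
  row <- data.frame(rho0 = test$rho0_hat, rho1 = test$rho1_hat,
                    z = test$z_stat, p = test$p_value,
                    reject = test$reject)
  if (!is.null(json_path))
    jsonlite::write_json(unclass(test), json_path, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(tsv_path))
    data.table::fwrite(row, tsv_path, sep = "\t")
  invisible(row)
}
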