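#' Configuration of a block-sparse differential-association simulation
#'
#' Describes the generative scheme used throughout the package's power and
#' robustness studies: X is drawn from a p-dimensional normal, and Y given
#' group g follows `Normal(X B_g, Sigma_q)` where the p x q coefficient
#' matrices `B_0`, `B_1` are zero outside a small number of dense,
#' non-overlapping blocks. The three regimes differ in how the blocks of
#' `B_0` and `B_1` relate:
#' \describe{
#'   \item{`opposite_sign`}{`B_0 = +c`, `B_1 = -c` inside blocks: the
#'     association flips direction between groups (noiseless canonical
#'     correlations +1 and -1).}
#'   \item{`single_group`}{`B_0 = 0`, `B_1 = -c`: the association exists
#'     only in group 1 (noiseless correlations 0 and -1).}
#'   \item{`null`}{`B_0 = B_1 = -c`: association present but identical in
#'     both groups; used to measure the false positive rate of the
#'     difference test.}
#' }
#'
#' @param p,q Numbers of X and Y features (defaults 200 and 400).
#' @param n0,n1 Group sizes (defaults 200 and 200).
#' @param blocks List of `c(px, qx)` block sizes (defaults
#'   `list(c(10, 20), c(5, 10))`); blocks occupy disjoint leading index
#'   ranges on both sides.
#' @param setting `"opposite_sign"`, `"single_group"` or `"null"`.
#' @param coef_magnitude Magnitude c of the non-zero coefficients (default 1).
#' @param noise_sd Standard deviation of the Y noise (default 0.5, i.e.
#'   `Sigma_q = noise_sd^2 I` under the identity structure).
#' @param sigma_p_structure,sigma_q_structure `"identity"` (default) or
#'   `"ar1"` for an AR(1) correlation structure.
#' @param ar1_rho AR(1) correlation parameter when either structure is
#'   `"ar1"` (default 0.3).
#' @param seed Integer seed making [generate_paired_data()] deterministic.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(p = 200, q = 400, n0 = 200, n1 = 200,
                              blocks = list(c(10, 20), c(5, 10)),
                              setting = c("opposite_sign", "single_group",
                                          "null"),
                              coef_magnitude = 1, noise_sd = 0.5,
                              sigma_p_structure = c("identity", "ar1"),
                              sigma_q_structure = c("identity", "ar1"),
                              ar1_rho = 0.3, seed = 1) {
  setting <- match.arg(setting)
  stopifnot(p >= 1, q >= 1, n0 >= 2, n1 >= 2,
            coef_magnitude > 0, noise_sd > 0, length(blocks) >= 1)
  px <- vapply(blocks, `[`, numeric(1), 1L)
  qx <- vapply(blocks, `[`, numeric(1), 2L)
  if (any(px < 1) || any(qx < 1)) stop("block sizes must be positive")
  if (sum(px) > p || sum(qx) > q)
    stop("blocks exceed the available dimensions (sum px = ", sum(px),
         " vs p = ", p, "; sum qx = ", sum(qx), " vs q = ", q, ")")
  structure(list(p = p, q = q, n0 = n0, n1 = n1, blocks = blocks,
                 setting = setting, coef_magnitude = coef_magnitude,
                 noise_sd = noise_sd,
                 sigma_p_structure = match.arg(sigma_p_structure),
                 sigma_q_structure = match.arg(sigma_q_structure),
                 ar1_rho = ar1_rho, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$setting, "setting; p =", x$p, ", q =", x$q,
      ", n0 =", x$n0, ", n1 =", x$n1, "\n")
  cat("  blocks:", paste(vapply(x$blocks, function(b)
    paste0(b[1], "x", b[2]), character(1)), collapse = ", "),
    "; c =", x$coef_magnitude, ", noise sd =", x$noise_sd, "\n")
  invisible(x)
}

.block_layout <- function(config) {
  px <- vapply(config$blocks, `[`, numeric(1), 1L)
  qx <- vapply(config$blocks, `[`, numeric(1), 2L)
  x_end <- cumsum(px); x_start <- x_end - px + 1L
  y_end <- cumsum(qx); y_start <- y_end - qx + 1L
  lapply(seq_along(px), function(k)
    list(x = seq.int(x_start[k], x_end[k]),
         y = seq.int(y_start[k], y_end[k])))
}

.coef_matrices <- function(config) {
  c0 <- switch(config$setting,
               opposite_sign = config$coef_magnitude,
               single_group = 0,
               null = -config$coef_magnitude)
  c1 <- -config$coef_magnitude
  B0 <- matrix(0, config$p, config$q)
  B1 <- matrix(0, config$p, config$q)
  for (blk in .block_layout(config)) {
    B0[blk$x, blk$y] <- c0
    B1[blk$x, blk$y] <- c1
  }
  list(B0 = B0, B1 = B1)
}

.ar1_chol <- function(d, rho) {
  S <- rho^abs(outer(seq_len(d), seq_len(d), "-"))
  chol(S)
}

#' Generate one simulated paired dataset
#'
#' Draws `X ~ Normal(0, Sigma_p)` for all `n0 + n1` samples and
#' `Y_i ~ Normal(X_i B_{z_i}, noise_sd^2 Sigma_q)` row-wise, under the
#' regime described by the configuration. Deterministic given
#' `config$seed`.
#'
#' @param config A [simulation_config].
#' @return A list with `data` (a [paired_omics]; the first `n0` rows are
#'   group 0) and `truth`, a `truth_mask` list holding `active_x`,
#'   `active_y` (indices of block-member features), `block_of_x`,
#'   `block_of_y` (0 = inactive), and the theoretical noiseless
#'   correlations `rho0_true`, `rho1_true`.
#' @export
generate_paired_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n0 + config$n1
  z <- rep(c(0, 1), c(config$n0, config$n1))
  X <- matrix(stats::rnorm(n * config$p), n, config$p)
  if (config$sigma_p_structure == "ar1")
    X <- X %*% .ar1_chol(config$p, config$ar1_rho)

  E <- matrix(stats::rnorm(n * config$q, sd = config$noise_sd), n, config$q)
  if (config$sigma_q_structure == "ar1")
    E <- E %*% .ar1_chol(config$q, config$ar1_rho)

  B <- .coef_matrices(config)
  Y <- matrix(0, n, config$q)
  i0 <- z == 0
  Y[i0, ] <- X[i0, , drop = FALSE] %*% B$B0
  Y[!i0, ] <- X[!i0, , drop = FALSE] %*% B$B1
  Y <- Y + E

  layout <- .block_layout(config)
  block_of_x <- integer(config$p)
  block_of_y <- integer(config$q)
  for (k in seq_along(layout)) {
    block_of_x[layout[[k]]$x] <- k
    block_of_y[layout[[k]]$y] <- k
  }
  rho0_true <- switch(config$setting,
                      opposite_sign = 1, single_group = 0, null = -1)
  truth <- structure(list(active_x = which(block_of_x > 0),
                          active_y = which(block_of_y > 0),
                          block_of_x = block_of_x, block_of_y = block_of_y,
                          rho0_true = rho0_true, rho1_true = -1),
                     class = "truth_mask")

  list(data = paired_omics(X, Y, z), truth = truth)
}

#' Precision, recall and F1 of feature selection against the truth
#'
#' @param selected_x,selected_y Integer index sets of selected features
#'   (e.g. the retained sets of a [screen_bicliques()] result).
#' @param truth A `truth_mask` from [generate_paired_data()].
#' @return A named list with `precision_x`, `recall_x`, `f1_x` and the Y
#'   analogues. An empty selection yields precision 0 with a warning.
#' @export
selection_metrics <- function(selected_x, selected_y, truth) {
  stopifnot(inherits(truth, "truth_mask"))
  one_side <- function(sel, active, side) {
    if (!length(sel)) {
      warning("empty ", side, " selection; precision set to 0")
      return(c(precision = 0, recall = 0, f1 = 0))
    }
    tp <- length(intersect(sel, active))
    prec <- tp / length(sel)
    rec <- tp / length(active)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  mx <- one_side(selected_x, truth$active_x, "X")
  my <- one_side(selected_y, truth$active_y, "Y")
  list(precision_x = mx[["precision"]], recall_x = mx[["recall"]],
       f1_x = mx[["f1"]],
       precision_y = my[["precision"]], recall_y = my[["recall"]],
       f1_y = my[["f1"]])
}

#' Run one replicate of the screen-then-fit pipeline
#'
#' Generates a dataset from `config`, screens it, selects the tuning
#' parameter by cross-validation on the retained features, fits dCCA per
#' biclique, and computes the replicate-level metrics. Selection metrics
#' compare the screening-retained features against the truth; the
#' canonical-correlation estimates, the difference test and the
#' classification AUC are based on the leading (largest-KL) block's
#' canonical pair. When screening retains nothing, dCCA runs unscreened on
#' all features. Used by [run_experiment()] and by the acceptance script.
#'
#' @param config A [simulation_config] (its `seed` controls this replicate).
#' @param method_opts List of pipeline options; recognized entries
#'   `r`, `max_blocks`, `lambda_grid` (screening), `cv_grid`, `cv_folds`
#'   (tuning), `weight`, `alpha`.
#' @return A one-row data frame of metrics plus the fitted objects in
#'   attributes `solutions` and `screen`.
#' @export
run_replicate <- function(config, method_opts = list()) {
  o <- utils::modifyList(list(r = NULL, max_blocks = 3,
                              lambda_grid = seq(0.5, 1.5, by = 0.1),
                              cv_grid = c(0, 0.25, 0.5, 1, 2, 4),
                              cv_folds = 5, weight = "group_max",
                              alpha = 0.05),
                         method_opts)
  gen <- generate_paired_data(config)
  data <- standardize_columns(gen$data, "pooled")
  truth <- gen$truth

  screen <- screen_bicliques(data, r = o$r, max_blocks = o$max_blocks,
                             lambda_grid = o$lambda_grid, weight = o$weight)

  if (length(screen$bicliques)) {
    sel <- selection_metrics(screen$retained_x, screen$retained_y, truth)
    sub <- subset_features(data, screen$retained_x, screen$retained_y)
    cv <- select_lambda_cv(sub, grid = o$cv_grid, folds = o$cv_folds,
                           seed = config$seed)
    solutions <- fit_all_blocks(data, screen, lam = cv$lambda)
    lead <- which.max(screen$kl[vapply(solutions, `[[`, integer(1),
                                       "block_id")])
    sol <- solutions[[lead]]
  } else {
    sel <- suppressWarnings(
      selection_metrics(integer(0), integer(0), truth))
    cv <- select_lambda_cv(data, grid = o$cv_grid, folds = o$cv_folds,
                           seed = config$seed)
    sol <- fit_dcca(data, lam = cv$lambda)
    solutions <- list(sol)
  }

  auc <- classification_auc(sol, data)
  dt <- test_difference(sol$rho0, sol$rho1, config$n0, config$n1,
                        alpha = o$alpha)
  row <- data.frame(sel,
                    rho0_hat = sol$rho0, rho1_hat = sol$rho1,
                    bias0 = abs(truth$rho0_true - sol$rho0),
                    bias1 = abs(truth$rho1_true - sol$rho1),
                    auc = as.numeric(auc),
                    lambda = sol$lam,
                    n_blocks = length(screen$bicliques),
                    p_diff = dt$p_value,
                    reject = dt$reject,
                    seed = config$seed)
  attr(row, "solutions") <- solutions
  attr(row, "screen") <- screen
  row
}

#' Replicated simulation experiment
#'
#' Repeats [run_replicate()] over independent seeds and aggregates the
#' selection metrics, canonical-correlation biases, classification AUC and
#' (for the null regime) the false positive rate of the difference test.
#'
#' @param config A [simulation_config]; per-replicate seeds are derived
#'   deterministically from `config$seed` unless `seeds` is given.
#' @param n_replicates Number of replicates.
#' @param method_opts Passed to [run_replicate()].
#' @param seeds Optional integer vector of length `n_replicates`.
#' @return An object of class `dcca_metrics`: a list with `summary` (mean
#'   and sd of each metric), `fpr` (rejection fraction at the test level),
#'   `per_replicate` (data frame), `n_failed`, `seeds` and `config`.
#' @export
run_experiment <- function(config, n_replicates, method_opts = list(),
                           seeds = NULL) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 1)
  if (is.null(seeds)) {
    old <- .Random.seed_save()
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    .Random.seed_restore(old)
  }
  if (length(seeds) != n_replicates)
    stop("seeds must have length n_replicates")

  rows <- vector("list", n_replicates)
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    rows[[i]] <- tryCatch(run_replicate(cfg, method_opts),
                          error = function(e) {
                            failures <<- c(failures, conditionMessage(e))
                            NULL
                          })
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("all replicates failed; first error: ", failures[1])
  if (length(failures))
    warning(length(failures), " replicate(s) failed and were excluded")
  per <- do.call(rbind, rows[ok])
  attr(per, "solutions") <- NULL
  attr(per, "screen") <- NULL

  metric_cols <- c("precision_x", "recall_x", "f1_x",
                   "precision_y", "recall_y", "f1_y",
                   "bias0", "bias1", "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per[[m]]), numeric(1)),
    row.names = NULL)

  structure(list(summary = summary,
                 fpr = mean(per$reject),
                 per_replicate = per,
                 n_failed = length(failures),
                 seeds = seeds[ok],
                 config = config),
            class = "dcca_metrics")
}

#' @export
print.dcca_metrics <- function(x, ...) {
  cat("dcca_metrics:", nrow(x$per_replicate), "replicate(s),",
      x$config$setting, "setting\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f (%.2f)\n", s$metric[i], s$mean[i], s$sd[i]))
  if (x$config$setting == "null")
    cat(sprintf("  FPR at alpha: %.3f\n", x$fpr))
  if (x$n_failed) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}

#' Write an experiment's metrics table and metadata sidecar
#'
#' @param metrics A `dcca_metrics` object.
#' @param tsv_path Path for the per-replicate metrics TSV.
#' @param json_path Optional path for a JSON sidecar with the summary,
#'   seeds and configuration.
#' @return Invisibly, `tsv_path`.
#' @export
write_metrics <- function(metrics, tsv_path, json_path = NULL) {
  stopifnot(inherits(metrics, "dcca_metrics"))
  data.table::fwrite(metrics$per_replicate, tsv_path, sep = "\t")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(summary = metrics$summary, fpr = metrics$fpr,
           seeds = metrics$seeds, config = unclass(metrics$config),
           n_failed = metrics$n_failed),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
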