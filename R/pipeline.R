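#' Serialize a fitted dCCA solution
#'
#' @param solution A `dcca_solution`.
#' @param json_path Optional path for a JSON file with the named loadings,
#'   tuning parameter, canonical correlations and convergence metadata.
#' @param tsv_path Optional path for a two-column TSV of loadings
#'   (`feature`, `loading`; X features first, then Y features).
#' @return Invisibly, the list that was (or would be) written as JSON.
#' @export
write_solution <- function(solution, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(solution, "dcca_solution"))
  payload <- list(
    lambda = solution$lam,
    block_id = solution$block_id,
    u = as.list(solution$u),
    v = as.list(solution$v),
    rho_pooled = solution$rho_pooled,
    rho0 = solution$rho0,
    rho1 = solution$rho1,
    objective = solution$objective,
    n_iter = solution$n_iter,
    converged = solution$converged,
    sign_branch = solution$trace$sign_branch)
  if (!is.null(json_path))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    data.table::fwrite(
      data.frame(feature = c(names(solution$u), names(solution$v)),
                 side = rep(c("X", "Y"),
                            c(length(solution$u), length(solution$v))),
                 loading = c(unname(solution$u), unname(solution$v))),
      tsv_path, sep = "\t")
  invisible(payload)
}

#' Run the full screen-fit-test workflow on files
#'
#' End-to-end pipeline: load the paired dataset, standardize, optionally
#' screen by quasi-bicliques, choose the tuning parameter by stratified
#' cross-validation (unless a fixed `lambda` is given), fit dCCA per block
#' (or on all features when screening is disabled or retains nothing), test
#' the between-group difference of canonical correlations for every block,
#' and write all artifacts to `out_dir`:
#' `screen.tsv`, `edges.tsv`, `solution_block<k>.json` / `.tsv`,
#' `diff_test.tsv`, and a human-readable `summary.txt`.
#'
#' @param x_path,y_path,z_path Input files, see [load_paired_data()].
#' @param out_dir Output directory (created if absent).
#' @param screen Run the screening step? Default `TRUE`; set `FALSE` when
#'   `max(p, q) < n` and the noise level is low.
#' @param r,max_blocks,lambda_grid Screening options, see
#'   [screen_bicliques()].
#' @param lambda Fixed tuning parameter; `NULL` (default) selects it by
#'   cross-validation over `cv_grid`.
#' @param cv_grid,cv_folds,seed Cross-validation options, see
#'   [select_lambda_cv()].
#' @param max_iter,tol Optimizer options, see [fit_dcca()].
#' @return Invisibly, a list with `screen`, `lambda`, `solutions`, `tests`
#'   and the paths of the written files. On error, partial outputs in
#'   `out_dir` from this invocation are removed.
#' @export
run_pipeline <- function(x_path, y_path, z_path, out_dir,
                         screen = TRUE, r = NULL, max_blocks = 3,
                         lambda_grid = seq(0.5, 1.5, by = 0.1),
                         lambda = NULL, cv_grid = c(0, 0.25, 0.5, 1, 2, 4),
                         cv_folds = 5, seed = 1, max_iter = 500,
                         tol = 1e-8) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_error <- function(e) {
    file.remove(written[file.exists(written)])
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    data <- load_paired_data(x_path, y_path, z_path)
    data <- standardize_columns(data, "pooled")

    scr <- NULL
    if (screen && max_blocks > 0) {
      scr <- screen_bicliques(data, r = r, max_blocks = max_blocks,
                              lambda_grid = lambda_grid)
      p1 <- file.path(out_dir, "screen.tsv")
      data.table::fwrite(screen_table(scr), p1, sep = "\t")
      p2 <- file.path(out_dir, "edges.tsv")
      data.table::fwrite(screen_edge_list(scr), p2, sep = "\t")
      written <- c(written, p1, p2)
    }

    screened <- !is.null(scr) && length(scr$bicliques) > 0
    fit_data <- if (screened)
      subset_features(data, scr$retained_x, scr$retained_y) else data

    if (is.null(lambda)) {
      cv <- select_lambda_cv(fit_data, grid = cv_grid, folds = cv_folds,
                             seed = seed, max_iter = max_iter, tol = tol)
      lambda <- cv$lambda
    }

    solutions <- if (screened)
      fit_all_blocks(data, scr, lam = lambda, max_iter = max_iter,
                     tol = tol)
    else
      list(fit_dcca(data, lam = lambda, max_iter = max_iter, tol = tol))

    tests <- list()
    rows <- list()
    n0 <- sum(data$z == 0); n1 <- sum(data$z == 1)
    for (i in seq_along(solutions)) {
      sol <- solutions[[i]]
      tag <- if (is.na(sol$block_id)) i else sol$block_id
      pj <- file.path(out_dir, paste0("solution_block", tag, ".json"))
      pt <- file.path(out_dir, paste0("solution_block", tag, ".tsv"))
      write_solution(sol, pj, pt)
      written <- c(written, pj, pt)
      dt <- test_difference(sol$rho0, sol$rho1, n0, n1)
      tests[[i]] <- dt
      rows[[i]] <- data.frame(block = tag, rho0 = dt$rho0_hat,
                              rho1 = dt$rho1_hat, z = dt$z_stat,
                              p = dt$p_value, reject = dt$reject)
    }
    ptest <- file.path(out_dir, "diff_test.tsv")
    data.table::fwrite(do.call(rbind, rows), ptest, sep = "\t")
    written <- c(written, ptest)

    psum <- file.path(out_dir, "summary.txt")
    con <- file(psum, "w")
    sink(con)
    cat("dCCA pipeline summary\n=====================\n")
    print(data)
    if (!is.null(scr)) print(scr)
    cat("tuning lambda:", lambda, "\n\n")
    for (i in seq_along(solutions)) {
      print(solutions[[i]])
      print(tests[[i]])
    }
    sink()
    close(con)
    written <- c(written, psum)

    invisible(list(screen = scr, lambda = lambda, solutions = solutions,
                   tests = tests, files = written))
  }, error = on_error)
}
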