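#' Deterministic K-fold assignment
#'
#' @param n Number of samples.
#' @param K Number of folds, `2 <= K <= n`.
#' @param seed Integer seed; the same seed always yields the same
#'   assignment and the caller's RNG stream is left untouched.
#' @return Integer vector of length `n` with fold labels in `1..K`; fold
#'   sizes differ by at most one.
#' @export
make_folds <- function(n, K, seed = 1) {
  if (K < 2) stop("'K' must be at least 2")
  if (K > n) stop("'K' cannot exceed the number of samples")
  with_seed(seed, sample(rep(seq_len(K), length.out = n)))
}

#' Data-driven penalty grids
#'
#' Builds evenly spaced penalty grids spanning from a dense fit to the
#' penalty level at which the first update collapses to zero (the max-norm
#' of the unthresholded update, or half the range on zero-sum sides, where
#' the hyperplane absorbs a common shift). Even spacing follows the
#' penalized-matrix-decomposition tuning convention; a log-spaced grid
#' oversamples the near-zero dense tail, where every candidate fit uses
#' nearly all features and the cross-validated correlations are
#' indistinguishable.
#'
#' @param Y,Z Paired tables as passed to the fit functions.
#' @param two_sided Whether the `Y` side is compositional too.
#' @param nlam Grid length per side, default 10.
#' @param min_ratio Smallest penalty as a fraction of the collapse level,
#'   default 0.05.
#' @param max_ratio Largest penalty as a fraction of the collapse level,
#'   default 0.95.
#' @return `list(lam_a, lam_b)` of increasing penalty values.
#' @export
default_lambda_grid <- function(Y, Z, two_sided = FALSE, nlam = 10,
                                min_ratio = 0.05, max_ratio = 0.95) {
  S <- cross_covariance(Y, Z)
  a0 <- initialize_a(S)
  hb <- drop(crossprod(S, a0))
  lam_b_max <- (max(hb) - min(hb)) / 2      # zero-sum side collapse level
  b0 <- prox_zero_sum_weighted_l1(hb, 0)
  b0 <- b0 / l2norm(b0)
  va <- drop(S %*% b0)
  lam_a_max <- if (two_sided) (max(va) - min(va)) / 2 else max(abs(va))
  ratios <- seq(min_ratio, max_ratio, length.out = nlam)
  list(lam_a = lam_a_max * ratios, lam_b = lam_b_max * ratios)
}

# Evaluate every grid row on one fold. The training cross-covariance is
# computed once and shared across the grid; the stage-2 restriction to the
# stage-1 supports is a submatrix of it (column subsetting commutes with
# centering). Returns a numeric vector of held-out correlations, 0 for
# degenerate rows.
cv_eval_fold <- function(Ym, Zm, test_idx, grid, method, groups, groups_a,
                         two_sided, C_U, opts) {
  tr <- setdiff(seq_len(nrow(Ym)), test_idx)
  S_tr <- cross_covariance(Ym[tr, , drop = FALSE], Zm[tr, , drop = FALSE])
  a0 <- tryCatch(initialize_a(S_tr), error = function(e) NULL)
  if (is.null(a0)) return(rep(0, nrow(grid)))
  # zero-sum sides need at least two selected features to stay feasible
  min_a <- if (method != "scca" && two_sided) 2L else 1L
  min_b <- if (method != "scca") 2L else 1L
  vapply(seq_len(nrow(grid)), function(i) {
    eng1 <- tryCatch(
      suppressWarnings(engine_for_method(
        S_tr, method, lam_a = grid$lam_a[i], lam_b = grid$lam_b[i],
        gamma = grid$gamma[i], groups = groups, groups_a = groups_a,
        two_sided = two_sided, C_U = C_U, opts = opts, a_init = a0)),
      error = function(e) NULL)
    if (is.null(eng1)) return(0)
    sa <- support_of(eng1$a); sb <- support_of(eng1$b)
    if (length(sa) < min_a || length(sb) < min_b) return(0)
    refit <- if (method == "scca") "scca" else "cscca"
    eng2 <- tryCatch(
      suppressWarnings(engine_for_method(
        S_tr[sa, sb, drop = FALSE], refit, lam_a = 0, lam_b = 0,
        two_sided = two_sided, opts = opts)),
      error = function(e) NULL)
    if (is.null(eng2) || eng2$degenerate) return(0)
    sy <- drop(Ym[test_idx, sa, drop = FALSE] %*% eng2$a)
    sz <- drop(Zm[test_idx, sb, drop = FALSE] %*% eng2$b)
    if (sd(sy) == 0 || sd(sz) == 0) return(0)
    cor(sy, sz)
  }, numeric(1))
}

#' Two-stage cross-validation value for one tuning-parameter point
#'
#' For each fold: stage 1 fits the chosen method on the training samples
#' with the given penalties and records the supports; stage 2 refits on the
#' training samples restricted to those supports with zero penalties
#' (keeping the zero-sum constraint on compositional sides), removing the
#' shrinkage bias from the selection criterion; the Pearson correlation of
#' the held-out projected scores is then averaged over folds. Folds whose
#' stage-1 support is empty (or too small to satisfy the zero-sum
#' constraint) contribute 0.
#'
#' @param Y,Z Paired tables (log scale for compositional sides).
#' @param lam_a,lam_b Penalty levels.
#' @param gamma Adaptivity exponent for the adaptive variants (ignored
#'   otherwise).
#' @param folds Fold assignment from [make_folds()].
#' @param method One of `"scca"`, `"cscca"`, `"accca"`, `"sacca"`.
#' @param groups,groups_a,two_sided,C_U,opts Passed to [cca_fit()].
#' @return The K-fold mean held-out correlation.
#' @export
two_stage_cv_value <- function(Y, Z, lam_a, lam_b, gamma = 0.5, folds,
                               method = "cscca", groups = NULL,
                               groups_a = NULL, two_sided = FALSE,
                               C_U = 1e5, opts = solver_options()) {
  Ym <- om_values(Y); Zm <- om_values(Z)
  grid <- data.frame(lam_a = lam_a, lam_b = lam_b, gamma = gamma)
  vals <- vapply(sort(unique(folds)), function(k) {
    cv_eval_fold(Ym, Zm, which(folds == k), grid, method,
                 groups, groups_a, two_sided, C_U, opts)
  }, numeric(1))
  mean(vals)
}

#' Select tuning parameters by two-stage cross-validation
#'
#' Evaluates [two_stage_cv_value()] on every grid point (optionally
#' averaged over several independent fold partitions to reduce the
#' randomness of a single split) and returns the maximizer, ties broken by
#' grid order.
#'
#' @param Y,Z Paired tables.
#' @param grid Data frame with columns `lam_a`, `lam_b` and, for adaptive
#'   methods, `gamma`; or `NULL` to build a default grid via
#'   [default_lambda_grid()].
#' @param K Number of folds, default 5.
#' @param seed Integer seed driving the fold partitions.
#' @param method,groups,groups_a,two_sided,C_U,opts Passed to [cca_fit()].
#' @param n_replications Number of independent fold partitions to average
#'   over, default 1.
#' @param gamma_grid Gamma values crossed with the penalty grid when
#'   `grid = NULL` and the method is adaptive; default `c(0.5, 1)`.
#' @return A list of class `cv_result`: `grid` (with `mean_cv`, `sd_cv`),
#'   `chosen` (row of the best point), `cv_value`, `fold_assignments`
#'   (last partition used), `K`.
#' @export
select_tuning <- function(Y, Z, grid = NULL, K = 5, seed = 1,
                          method = "cscca", groups = NULL, groups_a = NULL,
                          two_sided = FALSE, C_U = 1e5,
                          opts = solver_options(), n_replications = 1,
                          gamma_grid = c(0.5, 1)) {
  Ym <- om_values(Y); Zm <- om_values(Z)
  n <- nrow(Ym)
  if (is.null(grid)) {
    lams <- default_lambda_grid(Y, Z, two_sided = two_sided)
    grid <- expand.grid(lam_a = lams$lam_a, lam_b = lams$lam_b)
    if (method %in% c("accca", "sacca"))
      grid <- merge(grid, data.frame(gamma = gamma_grid))
  }
  if (nrow(grid) == 0) stop("tuning grid is empty")
  if (is.null(grid$gamma)) grid$gamma <- 0.5
  cvmat <- matrix(NA_real_, nrow(grid), n_replications)
  folds <- NULL
  for (r in seq_len(n_replications)) {
    folds <- make_folds(n, K, seed + r - 1L)
    per_fold <- vapply(sort(unique(folds)), function(k)
      cv_eval_fold(Ym, Zm, which(folds == k), grid, method,
                   groups, groups_a, two_sided, C_U, opts),
      numeric(nrow(grid)))
    cvmat[, r] <- rowMeans(matrix(per_fold, nrow = nrow(grid)))
  }
  grid$mean_cv <- rowMeans(cvmat)
  grid$sd_cv <- apply(cvmat, 1, sd)
  if (all(grid$mean_cv == 0))
    stop("every grid point was degenerate; use a denser or weaker penalty grid")
  best <- which.max(grid$mean_cv)
  structure(list(grid = grid, chosen = grid[best, , drop = FALSE],
                 cv_value = grid$mean_cv[best],
                 fold_assignments = folds, K = K,
                 n_replications = n_replications),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold CV over %d grid points (%d partition%s)\n",
              x$K, nrow(x$grid), x$n_replications,
              if (x$n_replications > 1) "s" else ""))
  cat(sprintf("  chosen: lam_a = %.4g, lam_b = %.4g, gamma = %.3g, CV = %.4f\n",
              x$chosen$lam_a, x$chosen$lam_b, x$chosen$gamma, x$cv_value))
  invisible(x)
}

#' Write a cross-validation table
#'
#' @param cv A `cv_result` from [select_tuning()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cv_table <- function(cv, path) {
  write.table(cv$grid[, c("lam_a", "lam_b", "gamma", "mean_cv", "sd_cv")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
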