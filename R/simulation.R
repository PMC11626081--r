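#' Configuration of one simulation replicate
#'
#' The generative model ties the two feature tables together through a
#' scalar latent variable: `log X_i = nu_i * omega_X + eps_X` for the
#' compositional side and `Y_i = nu_i * omega_Y + eps_Y` (or
#' `log Y_i = ...` for the two-sided setups S3/S4), with
#' `nu_i ~ N(0, sigma_nu^2)` and isotropic `N(0, sigma_eps^2)` noise.
#' The ratio `sigma_nu / sigma_eps` sets the association strength.
#'
#' @param setup One of `"S1"`, `"S2"` (compositional vs non-compositional)
#'   or `"S3"`, `"S4"` (both compositional).
#' @param n Samples per replicate, default 100.
#' @param p,q Feature counts (compositional side `p`); both at least 10.
#' @param sigma_nu Latent-variable standard deviation (association
#'   strength), default 4.
#' @param sigma_eps Noise standard deviation, default 1.
#' @param seed Integer seed.
#' @param n_groups Number of taxonomic groups the `p` taxa form, default
#'   20 (group size 5 at p = 100, 10 at p = 200).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(setup = c("S1", "S2", "S3", "S4"), n = 100,
                              p = 100, q = 100, sigma_nu = 4, sigma_eps = 1,
                              seed = 1, n_groups = 20) {
  setup <- match.arg(setup)
  if (p < 10 || q < 10) stop("signal patterns occupy the first 10 coordinates; need p, q >= 10")
  if (p %% n_groups != 0) stop(sprintf("'n_groups' (%d) must divide p (%d) evenly", n_groups, p))
  stopifnot(n >= 2, sigma_nu >= 0, sigma_eps > 0)
  structure(list(setup = setup, n = as.integer(n), p = as.integer(p),
                 q = as.integer(q), sigma_nu = sigma_nu,
                 sigma_eps = sigma_eps, seed = as.integer(seed),
                 n_groups = as.integer(n_groups),
                 two_sided = setup %in% c("S3", "S4")),
            class = "simulation_config")
}

#' True loading vectors of the simulation setups
#'
#' All compositional-side loadings sum to zero (the association acts
#' through log-ratios). S1 puts the signal in the first 10 coordinates
#' (nine equal positives balanced by one large negative); S2 splits six
#' nonzero entries across the first two size-5 groups, so the group
#' structure is noisy; S3 pairs the S1 pattern with a zero-sum
#' compositional `omega_Y`; S4 uses the S2 pattern on both sides.
#'
#' @param setup One of `"S1".."S4"`.
#' @param p,q Feature counts, both at least 10.
#' @return `list(omega_X, omega_Y)`.
#' @export
make_omega <- function(setup = c("S1", "S2", "S3", "S4"), p, q) {
  setup <- match.arg(setup)
  if (p < 10 || q < 10) stop("need p, q >= 10")
  s1_x <- function(m) 0.85 / 10 * c(rep(1, 9), -9, rep(0, m - 10))
  s2_x <- function(m) 0.85 / 6 * c(1, 1, 1, 0, 0, 1, 1, -5, 0, 0, rep(0, m - 10))
  y_noncomp <- 0.85 * c(seq(0.08, 0.12, length.out = 10), rep(0, q - 10))
  switch(setup,
    S1 = list(omega_X = s1_x(p), omega_Y = y_noncomp),
    S2 = list(omega_X = s2_x(p), omega_Y = y_noncomp),
    S3 = list(omega_X = s1_x(p),
              omega_Y = 0.85 * c(seq(0.08, 0.12, by = 0.005), -0.9, rep(0, q - 10))),
    S4 = list(omega_X = s2_x(p), omega_Y = s2_x(q)))
}

#' Taxonomic group labels for the simulated taxa
#'
#' Contiguous blocks of equal size, mirroring taxa ordered by taxonomy.
#'
#' @param p Number of features.
#' @param n_groups Number of groups (must divide `p`), default 20.
#' @return Integer vector of group labels of length `p`.
#' @export
make_groups <- function(p, n_groups = 20) {
  if (p %% n_groups != 0) stop("'n_groups' must divide 'p' evenly")
  rep(seq_len(n_groups), each = p %/% n_groups)
}

#' Draw one dataset from the latent-variable model
#'
#' @param cfg A [simulation_config()].
#' @return A list with `logX` (n x p, log-scale compositional side), `Y`
#'   (n x q; log scale when the setup is two-sided), and `truth`:
#'   `support_x`, `support_y` (indices of nonzero loadings), `target_x`,
#'   `target_y` (unit-normalized loadings, the estimation targets),
#'   `omega_X`, `omega_Y`, and `two_sided`.
#' @export
simulate_dataset <- function(cfg) {
  om <- make_omega(cfg$setup, cfg$p, cfg$q)
  dat <- with_seed(cfg$seed, {
    nu <- rnorm(cfg$n, 0, cfg$sigma_nu)
    epsX <- matrix(rnorm(cfg$n * cfg$p, 0, cfg$sigma_eps), cfg$n, cfg$p)
    epsY <- matrix(rnorm(cfg$n * cfg$q, 0, cfg$sigma_eps), cfg$n, cfg$q)
    list(logX = outer(nu, om$omega_X) + epsX,
         Y = outer(nu, om$omega_Y) + epsY)
  })
  colnames(dat$logX) <- paste0("taxon", seq_len(cfg$p))
  colnames(dat$Y) <- paste0(if (cfg$two_sided) "taxonB" else "feat", seq_len(cfg$q))
  list(logX = dat$logX, Y = dat$Y,
       truth = list(support_x = which(om$omega_X != 0),
                    support_y = which(om$omega_Y != 0),
                    target_x = om$omega_X / l2norm(om$omega_X),
                    target_y = om$omega_Y / l2norm(om$omega_Y),
                    omega_X = om$omega_X, omega_Y = om$omega_Y,
                    two_sided = cfg$two_sided))
}

#' Variable-selection metrics against a known support
#'
#' Confusion counts of the estimated support against the true one over
#' `1..total_features`, and the standard summaries: TPR, FPR, precision,
#' and Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. MCC is defined
#' as 0 when any factor under the root vanishes; precision is 0 when
#' nothing is selected.
#'
#' @param estimated_support,true_support Integer index vectors, subsets of
#'   `1..total_features`.
#' @param total_features Number of candidate features.
#' @return A list of class `selection_metrics` with `TP`, `FP`, `TN`,
#'   `FN`, `TPR`, `FPR`, `MCC`, `Precision`.
#' @export
selection_metrics <- function(estimated_support, true_support, total_features) {
  est <- unique(as.integer(estimated_support))
  tru <- unique(as.integer(true_support))
  if (length(est) && (min(est) < 1 || max(est) > total_features))
    stop("estimated support indices out of range")
  if (length(tru) && (min(tru) < 1 || max(tru) > total_features))
    stop("true support indices out of range")
  TP <- length(intersect(est, tru))
  FP <- length(setdiff(est, tru))
  FN <- length(setdiff(tru, est))
  TN <- total_features - TP - FP - FN
  TPR <- if (TP + FN == 0) 0 else TP / (TP + FN)
  FPR <- if (FP + TN == 0) 0 else FP / (FP + TN)
  Precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom == 0) 0 else (TP * TN - FP * FN) / sqrt(denom)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = TPR, FPR = FPR, MCC = MCC, Precision = Precision),
            class = "selection_metrics")
}

#' Root mean square error against a normalized target
#'
#' Compares a unit-norm estimate with `omega / ||omega||_2`, resolving the
#' global sign indeterminacy by taking the smaller of the two RMSEs; a
#' degenerate (all-zero) estimate is compared as-is.
#'
#' @param estimate Estimated direction (unit l2 norm or the zero vector).
#' @param omega True loading vector (nonzero).
#' @return The sign-aligned RMSE.
#' @export
rmse_to_target <- function(estimate, omega) {
  if (all(omega == 0)) stop("'omega' must be nonzero")
  if (length(estimate) != length(omega)) stop("length mismatch")
  target <- omega / l2norm(omega)
  if (all(estimate == 0)) return(sqrt(mean(target^2)))
  min(sqrt(mean((estimate - target)^2)), sqrt(mean((estimate + target)^2)))
}

# Tune, fit, and score one simulated replicate. Returns a one-row
# data.frame of metrics for both sides. Cross-validation fits run at a
# looser tolerance than the final fit: only the stage-1 supports and the
# held-out score correlations are consumed, and both are stable well
# before the directions converge to the final-fit precision.
evaluate_replicate <- function(cfg, method, K = 5, nlam = 10,
                               gamma_grid = c(0.5, 1), n_replications = 1,
                               C_U = 1e5, opts = solver_options(),
                               cv_opts = solver_options(
                                 outer_tol = 1e-4, max_outer_iter = 100,
                                 prox_opts = prox_options(inner_tol = 1e-6))) {
  dat <- simulate_dataset(cfg)
  groups <- make_groups(cfg$p, cfg$n_groups)
  groups_a <- if (dat$truth$two_sided && method == "sacca")
    make_groups(cfg$q, cfg$n_groups) else NULL
  lams <- default_lambda_grid(dat$Y, dat$logX, two_sided = dat$truth$two_sided,
                              nlam = nlam)
  grid <- expand.grid(lam_a = lams$lam_a, lam_b = lams$lam_b)
  if (method %in% c("accca", "sacca"))
    grid <- merge(grid, data.frame(gamma = gamma_grid))
  cv <- select_tuning(dat$Y, dat$logX, grid = grid, K = K,
                      seed = cfg$seed + 1L, method = method,
                      groups = if (method == "sacca") groups else NULL,
                      groups_a = groups_a, two_sided = dat$truth$two_sided,
                      C_U = C_U, opts = cv_opts, n_replications = n_replications)
  fit <- cca_fit(dat$Y, dat$logX, method = method,
                 lam_a = cv$chosen$lam_a, lam_b = cv$chosen$lam_b,
                 gamma = cv$chosen$gamma,
                 groups = if (method == "sacca") groups else NULL,
                 groups_a = groups_a, two_sided = dat$truth$two_sided,
                 C_U = C_U, opts = opts)
  mb <- selection_metrics(fit$support_b, dat$truth$support_x, cfg$p)
  ma <- selection_metrics(fit$support_a, dat$truth$support_y, cfg$q)
  data.frame(setup = cfg$setup, p = cfg$p, q = cfg$q,
             sigma_nu = cfg$sigma_nu, n = cfg$n, method = method,
             seed = cfg$seed,
             lam_a = cv$chosen$lam_a, lam_b = cv$chosen$lam_b,
             gamma = cv$chosen$gamma, cv_value = cv$cv_value,
             correlation = fit$sample_correlation,
             TPR_a = ma$TPR, FPR_a = ma$FPR, MCC_a = ma$MCC,
             Precision_a = ma$Precision,
             TPR_b = mb$TPR, FPR_b = mb$FPR, MCC_b = mb$MCC,
             Precision_b = mb$Precision,
             RMSE_a = rmse_to_target(fit$a, dat$truth$omega_Y),
             RMSE_b = rmse_to_target(fit$b, dat$truth$omega_X),
             stringsAsFactors = FALSE)
}

#' Run a simulation experiment over setups, dimensions and methods
#'
#' For every cell (setup x dimension x association strength x method),
#' draws `n_replicates` datasets, tunes each by two-stage K-fold
#' cross-validation, fits the tuned model, and scores support recovery
#' (TPR, FPR, MCC, precision, for both directions) and estimation accuracy
#' (RMSE against the unit-normalized loadings). Failed replicates are
#' recorded and skipped rather than aborting the run.
#'
#' @param setups Character vector of setups (`"S1".."S4"`).
#' @param dims List of `c(p, q)` pairs.
#' @param sigma_nu Numeric vector of association strengths.
#' @param methods Subset of `c("scca", "cscca", "accca", "sacca")`.
#' @param n_replicates Replicates per cell, default 30.
#' @param n Samples per replicate, default 100.
#' @param seed Base seed; every replicate's seed derives from it.
#' @param n_groups Number of taxonomic groups the compositional features
#'   form (must divide `p`), default 20.
#' @param K,nlam,gamma_grid,n_replications,C_U,opts Tuning controls passed
#'   through to [evaluate_replicate()]'s machinery.
#' @param verbose Print per-cell progress.
#' @return A list of class `experiment_result`: `replicates` (one row per
#'   replicate) and `summary` (long format: one row per cell x metric with
#'   mean and sd).
#' @export
run_experiment <- function(setups = "S1", dims = list(c(100, 100)),
                           sigma_nu = 4,
                           methods = c("scca", "cscca", "accca", "sacca"),
                           n_replicates = 30, n = 100, seed = 1,
                           n_groups = 20, K = 5,
                           nlam = 10, gamma_grid = c(0.5, 1),
                           n_replications = 1, C_U = 1e5,
                           opts = solver_options(), verbose = FALSE) {
  methods <- match.arg(methods, c("scca", "cscca", "accca", "sacca"),
                       several.ok = TRUE)
  rows <- list()
  errors <- list()
  cell_idx <- 0L
  for (setup in setups) for (d in dims) for (sn in sigma_nu) {
    cell_idx <- cell_idx + 1L
    for (method in methods) {
      if (verbose)
        message(sprintf("cell %s p=%d q=%d sigma_nu=%g method=%s",
                        setup, d[1], d[2], sn, method))
      for (i in seq_len(n_replicates)) {
        cfg <- simulation_config(setup, n = n, p = d[1], q = d[2],
                                 sigma_nu = sn, n_groups = n_groups,
                                 seed = seed + 7919L * cell_idx + i)
        res <- tryCatch(
          suppressWarnings(
            evaluate_replicate(cfg, method, K = K, nlam = nlam,
                               gamma_grid = gamma_grid,
                               n_replications = n_replications,
                               C_U = C_U, opts = opts)),
          error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1L]] <-
            data.frame(setup = setup, p = d[1], q = d[2], sigma_nu = sn,
                       method = method, replicate = i,
                       message = conditionMessage(res))
        } else {
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  if (!length(rows)) stop("every replicate failed")
  reps <- do.call(rbind, rows)
  metric_cols <- c("TPR_a", "FPR_a", "MCC_a", "Precision_a",
                   "TPR_b", "FPR_b", "MCC_b", "Precision_b",
                   "RMSE_a", "RMSE_b", "correlation")
  agg <- do.call(rbind, lapply(
    split(reps, interaction(reps$setup, reps$p, reps$q, reps$sigma_nu,
                            reps$method, drop = TRUE)),
    function(g) {
      do.call(rbind, lapply(metric_cols, function(m)
        data.frame(setup = g$setup[1], p = g$p[1], q = g$q[1],
                   sigma_nu = g$sigma_nu[1], method = g$method[1],
                   metric = m, mean = mean(g[[m]]), sd = sd(g[[m]]),
                   n_replicates = nrow(g), stringsAsFactors = FALSE)))
    }))
  rownames(agg) <- NULL
  structure(list(replicates = reps, summary = agg,
                 errors = if (length(errors)) do.call(rbind, errors) else NULL),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d replicates, %d summary rows\n",
              nrow(x$replicates), nrow(x$summary)))
  if (!is.null(x$errors))
    cat(sprintf("  %d failed replicates recorded\n", nrow(x$errors)))
  invisible(x)
}

#' Write experiment results as long-format TSV
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param path Output TSV path for the summary table.
#' @param replicates_path Optional TSV path for the per-replicate log.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(result, path, replicates_path = NULL) {
  write.table(result$summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(replicates_path))
    write.table(result$replicates, replicates_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
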