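#' Solver options for the alternating sparse CCA algorithms
#'
#' @param lam_a,lam_b Nonnegative l1 penalty levels for the two sides.
#' @param outer_tol Convergence tolerance on the max-norm change of both
#'   canonical directions, default 1e-6.
#' @param max_outer_iter Cap on alternating iterations, default 200.
#' @param prox_opts A [prox_options()] list controlling the zero-sum prox.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(lam_a = 0, lam_b = 0, outer_tol = 1e-6,
                           max_outer_iter = 200, prox_opts = prox_options()) {
  stopifnot(lam_a >= 0, lam_b >= 0, outer_tol > 0, max_outer_iter >= 1)
  structure(list(lam_a = lam_a, lam_b = lam_b, outer_tol = outer_tol,
                 max_outer_iter = as.integer(max_outer_iter),
                 prox_opts = prox_opts),
            class = "solver_options")
}

#' Feasible weight set for adaptive penalties
#'
#' Describes the constraint set M over which the per-feature penalty
#' weights are optimized: either the elementwise box `[0, C_U]^p` (plain
#' iterative adaptive lasso) or the group-structured set where weights are
#' shared within taxonomic groups (e.g. all genera of a phylum).
#'
#' @param kind One of `"none"`, `"elementwise_box"`, `"group"`.
#' @param groups For `kind = "group"`, a vector of group labels, one per
#'   feature (names are matched against feature ids when present).
#' @param C_U Upper bound on the weights; features with zero coefficient
#'   receive this cap. Default 1e5.
#' @param gamma Adaptivity exponent in (0, 1]; weights behave as
#'   `|b_j|^-gamma`.
#' @return A list of class `weight_constraint`.
#' @export
weight_constraint <- function(kind = c("none", "elementwise_box", "group"),
                              groups = NULL, C_U = 1e5, gamma = 0.5) {
  kind <- match.arg(kind)
  stopifnot(C_U > 0, gamma > 0, gamma <= 1)
  if (kind == "group") {
    if (is.null(groups)) stop("'groups' is required when kind = \"group\"")
    if (anyNA(groups)) stop("every feature must have exactly one group label")
  }
  structure(list(kind = kind, groups = groups, C_U = C_U, gamma = gamma),
            class = "weight_constraint")
}

l2norm <- function(x) sqrt(sum(x^2))

#' Initialize the left direction from the cross-covariance
#'
#' Returns the first left singular vector of the cross-covariance with unit
#' l2 norm, sign-fixed so its largest-magnitude entry (lowest index on
#' ties) is positive.
#'
#' @param S Cross-covariance matrix from [cross_covariance()].
#' @return Unit-norm numeric vector of length `nrow(S)`.
#' @export
initialize_a <- function(S) {
  S <- as.matrix(S)
  if (all(S == 0)) stop("cross-covariance is identically zero")
  a <- svd(S, nu = 1, nv = 0)$u[, 1]
  fix_sign(a / l2norm(a))
}

# Orient v so its largest-|.| entry (first on ties) is positive.
fix_sign <- function(v) {
  j <- which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' One compositional-side update
#'
#' Applies the zero-sum weighted-l1 prox to `t(S) %*% a` and renormalizes
#' to unit l2 norm; returns the zero vector with `degenerate = TRUE` when
#' the prox output vanishes.
#'
#' @param S Cross-covariance matrix (a-side features in rows).
#' @param a Current unit-norm left direction.
#' @param lam_b Penalty level.
#' @param w Weight vector (length `ncol(S)`).
#' @param opts A [prox_options()] list.
#' @param b_init Optional warm start for the prox.
#' @return `list(b, degenerate)`.
#' @export
update_b <- function(S, a, lam_b, w = rep(1, ncol(S)), opts = prox_options(),
                     b_init = NULL) {
  h <- drop(crossprod(S, a))
  braw <- prox_zero_sum_weighted_l1(h, lam_b, w, opts, b_init = b_init)
  nb <- l2norm(braw)
  if (nb == 0) return(list(b = rep(0, length(h)), degenerate = TRUE))
  list(b = as.numeric(braw) / nb, degenerate = FALSE)
}

#' One non-compositional-side update
#'
#' Soft-thresholds `S %*% b` and renormalizes. When the penalty meets or
#' exceeds the max-norm of the unthresholded vector the side collapses to
#' zero and the degenerate flag is set.
#'
#' @param S Cross-covariance matrix.
#' @param b Current unit-norm right direction.
#' @param lam_a Penalty level.
#' @param w Optional weight vector for adaptive penalties (default ones).
#' @return `list(a, degenerate)`.
#' @export
update_a <- function(S, b, lam_a, w = rep(1, nrow(S))) {
  v <- drop(S %*% b)
  araw <- soft_threshold(v, lam_a * w)
  na <- l2norm(araw)
  if (na == 0) return(list(a = rep(0, length(v)), degenerate = TRUE))
  list(a = araw / na, degenerate = FALSE)
}

#' Penalty function regularizing the adaptive weights
#'
#' `h(w; gamma)` couples the weight estimate to the coefficient magnitude:
#' minimizing `w * |b| - log h(w, gamma)` over `w` yields the adaptive-lasso
#' weight `|b|^-gamma`.
#'
#' @param w Positive weight value(s).
#' @param gamma Exponent in (0, 1].
#' @return `h(w; gamma)`: `exp(w^(1 - 1/gamma) / (1 - 1/gamma))` for
#'   `gamma < 1`, and `w` for `gamma = 1`.
#' @export
penalty_h <- function(w, gamma) {
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  if (gamma == 1) return(w)
  e <- 1 - 1 / gamma
  exp(w^e / e)
}

#' Data-driven penalty weights from current coefficients
#'
#' Minimizes `sum_j w_j |b_j| - log h(w_j, gamma)` over the feasible weight
#' set. Elementwise box: `w_j = |b_j|^-gamma`, capped at `C_U` (and set to
#' `C_U` when `b_j = 0`). Group set: one shared weight per group,
#' `(mean_j |b_j|)^-gamma` over the group's members, `C_U` when the whole
#' group is zero.
#'
#' @param b Current coefficient vector.
#' @param constraint A [weight_constraint()] with kind `"elementwise_box"`
#'   or `"group"`.
#' @return Weight vector of the same length as `b`.
#' @export
update_weights <- function(b, constraint) {
  if (constraint$kind == "none")
    stop("update_weights requires an elementwise_box or group constraint")
  C_U <- constraint$C_U
  gamma <- constraint$gamma
  if (constraint$kind == "elementwise_box") {
    w <- ifelse(b == 0, C_U, pmin(C_U, abs(b)^(-gamma)))
    return(as.numeric(w))
  }
  groups <- constraint$groups
  if (length(groups) != length(b))
    stop("group map must assign a group to every feature (lengths differ)")
  mb <- stats::ave(abs(b), groups)   # group means, expanded per feature
  as.numeric(ifelse(mb == 0, C_U, pmin(C_U, mb^(-gamma))))
}

# Internal alternating engine shared by all variants.
#
# zero_sum_a / zero_sum_b: enforce the zero-sum constraint on each side.
# constraint_a / constraint_b: weight_constraint for adaptive updates
#   (kind "none" means fixed weights w_a / w_b throughout).
cscca_engine <- function(S, opts,
                         zero_sum_a = FALSE, zero_sum_b = TRUE,
                         constraint_a = weight_constraint("none"),
                         constraint_b = weight_constraint("none"),
                         w_a = NULL, w_b = NULL, a_init = NULL) {
  S <- as.matrix(S)
  q <- nrow(S); p <- ncol(S)
  if (is.null(w_a)) w_a <- rep(1, q)
  if (is.null(w_b)) w_b <- rep(1, p)
  a <- if (is.null(a_init)) initialize_a(S) else a_init
  b <- rep(0, p)
  degenerate <- FALSE
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(opts$max_outer_iter)) {
    a_prev <- a; b_prev <- b
    # b side
    if (zero_sum_b) {
      ub <- update_b(S, a, opts$lam_b, w_b, opts$prox_opts,
                     b_init = if (iter > 1) b_prev else NULL)
    } else {
      h <- drop(crossprod(S, a))
      braw <- soft_threshold(h, opts$lam_b * w_b)
      nb <- l2norm(braw)
      ub <- if (nb == 0) list(b = rep(0, p), degenerate = TRUE)
            else list(b = braw / nb, degenerate = FALSE)
    }
    if (ub$degenerate) { b <- ub$b; degenerate <- TRUE; break }
    b <- ub$b
    if (constraint_b$kind != "none") w_b <- update_weights(b, constraint_b)
    # a side
    if (zero_sum_a) {
      v <- drop(S %*% b)
      araw <- prox_zero_sum_weighted_l1(v, opts$lam_a, w_a, opts$prox_opts,
                                        b_init = if (iter > 1) a_prev else NULL)
      na <- l2norm(araw)
      ua <- if (na == 0) list(a = rep(0, q), degenerate = TRUE)
            else list(a = as.numeric(araw) / na, degenerate = FALSE)
    } else {
      ua <- update_a(S, b, opts$lam_a, w_a)
    }
    if (ua$degenerate) { a <- ua$a; degenerate <- TRUE; break }
    a <- ua$a
    if (constraint_a$kind != "none") w_a <- update_weights(a, constraint_a)
    if (max(max(abs(a - a_prev)), max(abs(b - b_prev))) < opts$outer_tol) {
      converged <- TRUE
      break
    }
  }
  if (!degenerate && !converged)
    warning("alternating updates did not converge within max_outer_iter; returning last iterate")
  # resolve the global sign indeterminacy: largest-|.| entry of a positive
  if (!degenerate && any(a != 0)) {
    j <- which.max(abs(a))
    if (a[j] < 0) { a <- -a; b <- -b }
  }
  list(a = a, b = b, w_a = w_a, w_b = w_b,
       n_iterations = iter, converged = converged, degenerate = degenerate)
}

support_of <- function(x, tol = 1e-10) which(abs(x) > tol)

# Assemble a canonical_pair from engine output plus data for the achieved
# sample correlation.
make_pair <- function(eng, Y, Z, method, lam_a, lam_b, gamma = NA_real_) {
  Ym <- om_values(Y); Zm <- om_values(Z)
  r <- 0
  if (!eng$degenerate) {
    sy <- drop(Ym %*% eng$a); sz <- drop(Zm %*% eng$b)
    if (sd(sy) > 0 && sd(sz) > 0) r <- cor(sy, sz)
  }
  structure(list(a = eng$a, b = eng$b,
                 support_a = support_of(eng$a), support_b = support_of(eng$b),
                 sample_correlation = r,
                 n_iterations = eng$n_iterations,
                 converged = eng$converged, degenerate = eng$degenerate,
                 weights_a = eng$w_a, weights_b = eng$w_b,
                 method = method, lam_a = lam_a, lam_b = lam_b, gamma = gamma,
                 feature_ids_a = colnames(Ym), feature_ids_b = colnames(Zm)),
            class = "canonical_pair")
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat(sprintf("canonical_pair [%s]%s\n", x$method,
              if (x$degenerate) " (degenerate)" else ""))
  cat(sprintf("  |support(a)| = %d, |support(b)| = %d\n",
              length(x$support_a), length(x$support_b)))
  cat(sprintf("  sample correlation = %.4f, iterations = %d, converged = %s\n",
              x$sample_correlation, x$n_iterations, x$converged))
  invisible(x)
}

#' Compositional sparse CCA (compositional vs non-compositional)
#'
#' Alternates a zero-sum weighted-l1 prox update on the compositional side
#' with a soft-thresholding update on the non-compositional side, starting
#' from the leading left singular vector of the sample cross-covariance.
#' The zero-sum constraint on `b` makes the score `Z b` invariant to
#' per-sample scaling of the underlying composition, so no reference taxon
#' is needed.
#'
#' @param Y Non-compositional table (samples x q), an [omics_matrix()] or
#'   matrix.
#' @param Z Log-transformed compositional table (samples x p).
#' @param opts A [solver_options()] list carrying `lam_a`, `lam_b`.
#' @param w Optional fixed weight vector for the compositional penalty
#'   (default uniform).
#' @return A `canonical_pair` with directions `a` (for `Y`) and `b` (for
#'   `Z`), their supports, the achieved sample correlation and convergence
#'   diagnostics.
#' @export
fit_cscca <- function(Y, Z, opts = solver_options(), w = NULL) {
  check_paired_samples(Y, Z)
  S <- cross_covariance(Y, Z)
  eng <- cscca_engine(S, opts, zero_sum_a = FALSE, zero_sum_b = TRUE, w_b = w)
  make_pair(eng, Y, Z, "cscca", opts$lam_a, opts$lam_b)
}

#' Two-sided compositional sparse CCA (compositional vs compositional)
#'
#' Both directions are constrained to the zero-sum hyperplane and updated
#' through the weighted zero-sum prox, for pairing two compositional
#' datasets (e.g. bacterial vs fungal taxa).
#'
#' @param U,Z Log-transformed compositional tables (samples x q and
#'   samples x p).
#' @param opts A [solver_options()] list.
#' @param w1,w2 Optional fixed weights for the `U` (a) and `Z` (b) sides.
#' @return A `canonical_pair`; both directions are zero-sum.
#' @export
fit_cscca_two_sided <- function(U, Z, opts = solver_options(),
                                w1 = NULL, w2 = NULL) {
  check_paired_samples(U, Z)
  S <- cross_covariance(U, Z)
  eng <- cscca_engine(S, opts, zero_sum_a = TRUE, zero_sum_b = TRUE,
                      w_a = w1, w_b = w2)
  make_pair(eng, U, Z, "cscca_two_sided", opts$lam_a, opts$lam_b)
}

#' Structure-adaptive compositional sparse CCA
#'
#' Interleaves the compositional `b` update with a closed-form weight
#' update over the feasible set described by `constraint` (elementwise box
#' for plain adaptive weights, group set to share weights within taxonomic
#' groups), then updates `a`. Elementwise adaptive weights are also applied
#' on the `a` side with the same `C_U` and `gamma`. Weights start at one,
#' so the first iteration coincides with the non-adaptive fit.
#'
#' @param Y Non-compositional table (samples x q).
#' @param Z Log-transformed compositional table (samples x p).
#' @param opts A [solver_options()] list.
#' @param constraint A [weight_constraint()] for the compositional side;
#'   kind `"elementwise_box"` gives the adaptive variant, `"group"` the
#'   structure-adaptive variant.
#' @param adaptive_a Apply elementwise adaptive weights on the `a` side
#'   (default `TRUE`).
#' @return A list with elements `pair` (the `canonical_pair`) and
#'   `weights` (final penalty weights of the compositional side).
#' @export
fit_sacca <- function(Y, Z, opts = solver_options(),
                      constraint = weight_constraint("elementwise_box"),
                      adaptive_a = TRUE) {
  if (constraint$kind == "none")
    stop("fit_sacca needs an elementwise_box or group weight constraint")
  check_paired_samples(Y, Z)
  S <- cross_covariance(Y, Z)
  ca <- if (adaptive_a)
    weight_constraint("elementwise_box", C_U = constraint$C_U, gamma = constraint$gamma)
  else weight_constraint("none")
  eng <- cscca_engine(S, opts, zero_sum_a = FALSE, zero_sum_b = TRUE,
                      constraint_a = ca, constraint_b = constraint)
  pair <- make_pair(eng, Y, Z,
                    if (constraint$kind == "group") "sacca" else "accca",
                    opts$lam_a, opts$lam_b, constraint$gamma)
  list(pair = pair, weights = eng$w_b)
}

#' Two-sided structure-adaptive compositional sparse CCA
#'
#' As [fit_sacca()] but with both sides compositional: each direction is
#' updated through the zero-sum prox and carries its own adaptive weight
#' constraint.
#'
#' @param U,Z Log-transformed compositional tables.
#' @param opts A [solver_options()] list.
#' @param constraint_a,constraint_b [weight_constraint()]s for the `U` and
#'   `Z` sides.
#' @return A list with elements `pair`, `weights_a`, `weights_b`.
#' @export
fit_sacca_two_sided <- function(U, Z, opts = solver_options(),
                                constraint_a = weight_constraint("elementwise_box"),
                                constraint_b = weight_constraint("elementwise_box")) {
  if (constraint_a$kind == "none" || constraint_b$kind == "none")
    stop("both sides need an elementwise_box or group weight constraint")
  check_paired_samples(U, Z)
  S <- cross_covariance(U, Z)
  eng <- cscca_engine(S, opts, zero_sum_a = TRUE, zero_sum_b = TRUE,
                      constraint_a = constraint_a, constraint_b = constraint_b)
  method <- if (constraint_b$kind == "group" || constraint_a$kind == "group")
    "sacca_two_sided" else "accca_two_sided"
  pair <- make_pair(eng, U, Z, method, opts$lam_a, opts$lam_b, constraint_b$gamma)
  list(pair = pair, weights_a = eng$w_a, weights_b = eng$w_b)
}

#' Plain sparse CCA baseline (no compositional constraint)
#'
#' The diagonal-covariance penalized-matrix-decomposition scheme applied
#' symmetrically: both sides are updated by soft thresholding and l2
#' renormalization, with no zero-sum constraint. Serves as the
#' non-compositional comparator.
#'
#' @param Y,Z Paired tables (samples x q and samples x p).
#' @param opts A [solver_options()] list.
#' @return A `canonical_pair`.
#' @export
fit_scca_baseline <- function(Y, Z, opts = solver_options()) {
  check_paired_samples(Y, Z)
  S <- cross_covariance(Y, Z)
  eng <- cscca_engine(S, opts, zero_sum_a = FALSE, zero_sum_b = FALSE)
  make_pair(eng, Y, Z, "scca", opts$lam_a, opts$lam_b)
}

# Map a method name onto engine arguments and run it on a precomputed
# cross-covariance. Used by cca_fit and by the cross-validation loops,
# which reuse one covariance per fold across the whole tuning grid.
engine_for_method <- function(S, method, lam_a = 0, lam_b = 0, gamma = 0.5,
                              groups = NULL, groups_a = NULL,
                              two_sided = FALSE, C_U = 1e5,
                              opts = solver_options(), a_init = NULL) {
  opts$lam_a <- lam_a; opts$lam_b <- lam_b
  if (method == "scca")
    return(cscca_engine(S, opts, zero_sum_a = FALSE, zero_sum_b = FALSE,
                        a_init = a_init))
  if (method == "cscca")
    return(cscca_engine(S, opts, zero_sum_a = two_sided, zero_sum_b = TRUE,
                        a_init = a_init))
  cb <- if (method == "sacca") {
    if (is.null(groups)) stop("method \"sacca\" requires 'groups'")
    weight_constraint("group", groups = groups, C_U = C_U, gamma = gamma)
  } else weight_constraint("elementwise_box", C_U = C_U, gamma = gamma)
  ca <- if (method == "sacca" && two_sided && !is.null(groups_a))
    weight_constraint("group", groups = groups_a, C_U = C_U, gamma = gamma)
  else weight_constraint("elementwise_box", C_U = C_U, gamma = gamma)
  cscca_engine(S, opts, zero_sum_a = two_sided, zero_sum_b = TRUE,
               constraint_a = ca, constraint_b = cb, a_init = a_init)
}

#' Unified front end over the sparse CCA variants
#'
#' Dispatcher used by the cross-validation and simulation machinery.
#'
#' @param Y,Z Paired tables; `Z` (and `Y` when `two_sided`) on the log
#'   scale for compositional data.
#' @param method One of `"scca"`, `"cscca"`, `"accca"`, `"sacca"`.
#' @param lam_a,lam_b Penalty levels.
#' @param gamma Adaptivity exponent for the adaptive variants.
#' @param groups Group labels for the compositional (`Z`) side when
#'   `method = "sacca"`.
#' @param groups_a Group labels for the `Y` side of a two-sided
#'   structure-adaptive fit (defaults to elementwise weights).
#' @param two_sided Treat both sides as compositional.
#' @param C_U Weight cap for the adaptive variants.
#' @param opts Base [solver_options()]; `lam_a`, `lam_b` are overridden.
#' @return A `canonical_pair`.
#' @export
cca_fit <- function(Y, Z, method = c("cscca", "scca", "accca", "sacca"),
                    lam_a = 0, lam_b = 0, gamma = 0.5,
                    groups = NULL, groups_a = NULL, two_sided = FALSE,
                    C_U = 1e5, opts = solver_options()) {
  method <- match.arg(method)
  check_paired_samples(Y, Z)
  S <- cross_covariance(Y, Z)
  eng <- engine_for_method(S, method, lam_a = lam_a, lam_b = lam_b,
                           gamma = gamma, groups = groups,
                           groups_a = groups_a, two_sided = two_sided,
                           C_U = C_U, opts = opts)
  label <- switch(method,
                  scca = "scca",
                  cscca = if (two_sided) "cscca_two_sided" else "cscca",
                  accca = if (two_sided) "accca_two_sided" else "accca",
                  sacca = if (two_sided) "sacca_two_sided" else "sacca")
  make_pair(eng, Y, Z, label, lam_a, lam_b,
            if (method %in% c("accca", "sacca")) gamma else NA_real_)
}

#' Write / read a canonical-pair coefficient table
#'
#' Serializes a fitted pair to a TSV with columns `feature_id`, `side`,
#' `coefficient`, `weight`, and a JSON metadata record (penalties, gamma,
#' iterations, correlation) alongside when `metadata_path` is given.
#'
#' @param pair A `canonical_pair`.
#' @param path Output TSV path.
#' @param metadata_path Optional JSON path for the run metadata.
#' @param seed Optional seed to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(pair, path, metadata_path = NULL, seed = NULL) {
  ids_a <- pair$feature_ids_a %||% paste0("a", seq_along(pair$a))
  ids_b <- pair$feature_ids_b %||% paste0("b", seq_along(pair$b))
  df <- rbind(
    data.frame(feature_id = ids_a, side = "a", coefficient = pair$a,
               weight = pair$weights_a, stringsAsFactors = FALSE),
    data.frame(feature_id = ids_b, side = "b", coefficient = pair$b,
               weight = pair$weights_b, stringsAsFactors = FALSE))
  write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- list(method = pair$method, lam_a = pair$lam_a, lam_b = pair$lam_b,
                 gamma = pair$gamma, n_iterations = pair$n_iterations,
                 converged = pair$converged, degenerate = pair$degenerate,
                 sample_correlation = pair$sample_correlation,
                 package_version = as.character(utils::packageVersion("cscca")),
                 seed = seed)
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_coefficients
#' @return `read_coefficients()` returns the coefficient table as a
#'   data.frame.
#' @export
read_coefficients <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$coefficient <- as.numeric(df$coefficient)
  df$weight <- as.numeric(df$weight)
  df
}
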