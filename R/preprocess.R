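#' Replace zero counts with a pseudo-value
#'
#' Compositional tables must be strictly positive before the log transform.
#' Zero counts are replaced by a small positive value (0.5 on the count
#' scale is the conventional choice); nonzero entries are left untouched.
#'
#' @param X An [omics_matrix()] flagged compositional (or a plain matrix).
#' @param value Positive replacement value, default 0.5. If the table holds
#'   relative abundances rather than counts, supply a value on that scale.
#' @return The table with zeros replaced.
#' @export
replace_zeros <- function(X, value = 0.5) {
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    stop("'value' must be a single positive number")
  m <- om_values(X)
  if (inherits(X, "omics_matrix") && !X$compositional)
    stop("zero replacement is meant for compositional tables; flag X compositional")
  if (any(m < 0))
    stop("negative entries found; counts/abundances cannot be negative")
  m[m == 0] <- value
  if (inherits(X, "omics_matrix")) om_update(X, m) else m
}

#' Elementwise natural log transform
#'
#' @param X An [omics_matrix()] or matrix with strictly positive entries
#'   (apply [replace_zeros()] first for count tables).
#' @return The log-transformed table; the compositional flag is carried
#'   forward.
#' @export
log_transform <- function(X) {
  m <- om_values(X)
  if (any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive entry at sample '%s', feature '%s'; replace zeros first",
                 rownames(m)[idx[1]] %||% idx[1], colnames(m)[idx[2]] %||% idx[2]))
  }
  lm <- log(m)
  if (inherits(X, "omics_matrix")) om_update(X, lm) else lm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize columns to zero mean and unit variance
#'
#' Uses the unbiased (n-1) variance denominator.
#'
#' @param M An [omics_matrix()] or matrix with at least two samples.
#' @param center_only If `TRUE`, columns are centered but not scaled — the
#'   usual choice for log-compositional matrices where per-column scaling
#'   would distort the zero-sum interpretation of coefficients.
#' @return The standardized table.
#' @export
standardize <- function(M, center_only = FALSE) {
  m <- om_values(M)
  if (nrow(m) < 2) stop("standardization needs at least two samples")
  ctr <- scale(m, center = TRUE, scale = FALSE)
  if (!center_only) {
    s <- apply(m, 2, sd)
    bad <- which(s == 0)
    if (length(bad))
      stop("zero-variance column(s): ", paste(colnames(m)[bad] %||% bad, collapse = ", "),
           "; filter constant features first")
    ctr <- sweep(ctr, 2, s, "/")
  }
  out <- ctr
  attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  dimnames(out) <- dimnames(m)
  if (inherits(M, "omics_matrix")) om_update(M, out) else out
}

#' Filter features by prevalence
#'
#' Keeps features with nonzero abundance in at least `min_fraction` of
#' samples; applied to pre-log counts/abundances.
#'
#' @param X An [omics_matrix()] or matrix.
#' @param min_fraction Required presence fraction in (0, 1]; the common
#'   microbiome convention is 0.25 (present in at least a quarter of
#'   samples).
#' @return The filtered table, with attributes `n_kept` and `n_dropped`.
#' @export
prevalence_filter <- function(X, min_fraction = 0.25) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must be in (0, 1]")
  m <- om_values(X)
  prev <- colMeans(m != 0)
  keep <- prev >= min_fraction
  if (!any(keep))
    stop("prevalence filter would remove all features; lower 'min_fraction'")
  mk <- m[, keep, drop = FALSE]
  out <- if (inherits(X, "omics_matrix")) om_update(X, mk) else mk
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Sample cross-covariance between two tables
#'
#' Computes the q x p sample cross-covariance between the columns of `A`
#' and `B` (columns centered, 1/(n-1) scaling). This matrix drives every
#' solver update.
#'
#' @param A,B Paired [omics_matrix()] objects or matrices with the same
#'   samples in the same order; `A` contributes rows, `B` columns.
#' @return A numeric matrix with `row_ids`/`col_ids` as dimnames.
#' @export
cross_covariance <- function(A, B) {
  check_paired_samples(A, B)
  a <- om_values(A); b <- om_values(B)
  n <- nrow(a)
  if (n < 2) stop("cross-covariance needs at least two samples")
  S <- crossprod(scale(a, center = TRUE, scale = FALSE),
                 scale(b, center = TRUE, scale = FALSE)) / (n - 1)
  dimnames(S) <- list(colnames(a), colnames(b))
  S
}
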