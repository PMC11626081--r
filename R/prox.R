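#' Options for the zero-sum proximal solver
#'
#' @param mu1 Quadratic-penalty step of the augmented Lagrangian, default 1.
#' @param mu2 Dual-ascent step, default 1.
#' @param inner_tol Convergence tolerance for both the coordinate sweeps and
#'   the outer zero-sum residual, default 1e-8.
#' @param max_inner_iter Cap on coordinate-descent sweeps per outer
#'   iteration, default 1000.
#' @param max_alm_iter Cap on outer augmented-Lagrangian iterations,
#'   default 1000.
#' @return A list of class `prox_options`.
#' @export
prox_options <- function(mu1 = 1, mu2 = 1, inner_tol = 1e-8,
                         max_inner_iter = 1000, max_alm_iter = 1000) {
  stopifnot(mu1 > 0, mu2 > 0, inner_tol > 0,
            max_inner_iter >= 1, max_alm_iter >= 1)
  structure(list(mu1 = mu1, mu2 = mu2, inner_tol = inner_tol,
                 max_inner_iter = as.integer(max_inner_iter),
                 max_alm_iter = as.integer(max_alm_iter)),
            class = "prox_options")
}

#' Soft-thresholding operator
#'
#' `S(x, lam) = sign(x) * max(|x| - lam, 0)`, the proximal map of the
#' l1 penalty. Vectorized over `x`.
#'
#' @param x Numeric scalar or vector.
#' @param lam Nonnegative threshold (scalar, or vector recycled against `x`
#'   for weighted penalties).
#' @return Thresholded value(s).
#' @export
#' @examples
#' soft_threshold(3, 1)     # 2
#' soft_threshold(-0.5, 1)  # 0
soft_threshold <- function(x, lam) {
  if (any(lam < 0)) stop("'lam' must be nonnegative")
  sign(x) * pmax(abs(x) - lam, 0)
}

#' @rdname soft_threshold
#' @param v Numeric vector.
#' @export
soft_threshold_vector <- function(v, lam) soft_threshold(v, lam)

#' Proximal operator of the weighted l1 penalty on the zero-sum hyperplane
#'
#' Solves `argmin_{b : sum(b) = 0} 1/2 ||h - b||^2 + lam * sum_j w_j |b_j|`
#' by the augmented Lagrangian method: the dual variable of the zero-sum
#' constraint is updated by gradient ascent while each inner problem is
#' solved by cyclic coordinate descent with a closed-form soft-thresholding
#' update. This operator is the workhorse of every compositional update.
#'
#' @param h Numeric vector (length >= 2).
#' @param lam Nonnegative penalty level.
#' @param w Nonnegative weight vector of the same length as `h`; defaults
#'   to all ones.
#' @param opts A [prox_options()] list.
#' @param b_init Optional warm start; defaults to the zero-sum projection
#'   of `h` (`h - mean(h)`).
#' @return The minimizer, with attributes `iterations` and `residual`.
#' @export
#' @examples
#' prox_zero_sum_weighted_l1(c(1, 2, 3), 0)      # projection: c(-1, 0, 1)
prox_zero_sum_weighted_l1 <- function(h, lam, w = rep(1, length(h)),
                                      opts = prox_options(), b_init = NULL) {
  p <- length(h)
  if (p < 2) stop("'h' must have length >= 2")
  if (lam < 0) stop("'lam' must be nonnegative")
  if (length(w) != p) stop("'w' must have the same length as 'h'")
  if (any(!is.finite(w)) || any(w < 0)) stop("'w' must be finite and nonnegative")
  if (is.null(b_init)) b_init <- h - mean(h)
  res <- prox_zero_sum_cd(as.numeric(h), lam, as.numeric(w),
                          opts$mu1, opts$mu2, opts$inner_tol,
                          opts$max_inner_iter, opts$max_alm_iter,
                          as.numeric(b_init))
  if (!res$converged) {
    stop(structure(class = c("cscca_prox_error", "error", "condition"),
                   list(message = sprintf(
                          "zero-sum prox did not converge in %d outer iterations (|1'b| = %.3e)",
                          opts$max_alm_iter, res$residual),
                        call = sys.call(-1),
                        last_iterate = res$b, residual = res$residual)))
  }
  b <- res$b
  attr(b, "iterations") <- res$iterations
  attr(b, "residual") <- res$residual
  b
}
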