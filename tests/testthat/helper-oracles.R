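# Independent reference solvers used to check the package's optimizers.

# Zero-sum weighted-l1 prox via the Lagrangian dual: the stationarity
# conditions give b_j = S(h_j - theta, lam * w_j) for a scalar multiplier
# theta chosen so that sum(b) = 0; sum_j S(h_j - theta, lam*w_j) is
# continuous and nonincreasing in theta, so a 1-D root find solves the
# program exactly. Entirely independent of the augmented-Lagrangian
# coordinate-descent path under test.
prox_dual_oracle <- function(h, lam, w = rep(1, length(h))) {
  f <- function(theta) sum(soft_threshold(h - theta, lam * w))
  theta <- uniroot(f, c(min(h) - 1, max(h) + 1), tol = 1e-14)$root
  soft_threshold(h - theta, lam * w)
}

prox_objective <- function(b, h, lam, w = rep(1, length(h))) {
  0.5 * sum((h - b)^2) + lam * sum(w * abs(b))
}

# Noiseless rank-1 dataset from known directions (b_star zero-sum when the
# Z side is compositional).
rank1_data <- function(n = 40, a_star, b_star, seed = 1) {
  withr::with_seed(seed, {
    nu <- rnorm(n)
    list(Y = outer(nu, a_star), Z = outer(nu, b_star))
  })
}

unitize <- function(x) x / sqrt(sum(x^2))

# Max-norm distance after resolving the global sign.
sign_aligned_dist <- function(est, target) {
  min(max(abs(est - target)), max(abs(est + target)))
}
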