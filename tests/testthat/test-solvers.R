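test_that("initialization returns the sign-fixed leading left singular vector", {
  u <- unitize(c(2, -1, 0.5)); v <- unitize(c(1, 1, -3, 0.5))
  S <- outer(u, v)
  a0 <- initialize_a(S)
  expect_equal(abs(sum(a0 * u)), 1, tolerance = 1e-10)
  expect_gt(a0[which.max(abs(a0))], 0)
  # degenerate spectrum: first-index tie-break keeps a deterministic answer
  expect_equal(initialize_a(diag(2)), c(1, 0))
  withr::with_seed(3, S <- matrix(rnorm(30), 6, 5))
  ref <- svd(S)$u[, 1]
  if (ref[which.max(abs(ref))] < 0) ref <- -ref
  expect_equal(initialize_a(S), ref, tolerance = 1e-8)
  expect_error(initialize_a(matrix(0, 2, 2)), "zero")
})

test_that("compositional update projects, thresholds, and renormalizes", {
  # with lam 0 the prox is the zero-sum projection; (1,2,3) -> (-1,0,1)/sqrt2
  S <- diag(3)
  a <- c(1, 2, 3) / sqrt(14)
  res <- update_b(S * sqrt(14), a, 0)
  expect_equal(res$b, c(-1, 0, 1) / sqrt(2), tolerance = 1e-7)
  expect_false(res$degenerate)
  big <- update_b(S, c(1, 0, 0), lam_b = 50)
  expect_true(big$degenerate)
  expect_equal(big$b, rep(0, 3))
})

test_that("non-compositional update thresholds and flags the collapse boundary", {
  S <- rbind(c(3, 0), c(-1, 0))
  b <- c(1, 0)
  expect_equal(update_a(S, b, 1)$a, c(1, 0))
  # boundary lam_a = max|v| collapses to zero
  res <- update_a(S, b, 3)
  expect_true(res$degenerate)
  expect_equal(res$a, c(0, 0))
  expect_equal(update_a(S, b, 0)$a, c(3, -1) / sqrt(10))
})

test_that("weight penalty h and the closed-form weight updates are mutually consistent", {
  expect_equal(penalty_h(3, 1), 3)
  expect_equal(penalty_h(1, 0.5), exp(-1))
  expect_error(penalty_h(1, 1.2), "gamma")
  # stationarity: argmin_w w|b| - log h(w, gamma) equals |b|^-gamma
  for (babs in c(0.1, 0.5, 2)) for (gam in c(0.25, 0.5, 1)) {
    f <- function(w) w * babs - log(penalty_h(w, gam))
    wopt <- optimize(f, c(1e-6, 1e4), tol = 1e-10)$minimum
    expect_equal(wopt, babs^(-gam), tolerance = 1e-4)
  }
})

test_that("elementwise and group weight updates follow the closed forms", {
  ew <- weight_constraint("elementwise_box", gamma = 1)
  expect_equal(update_weights(c(0.25, 0, 0.5), ew), c(4, 1e5, 2))
  # capped when |b_j|^-gamma exceeds C_U
  ew2 <- weight_constraint("elementwise_box", gamma = 1, C_U = 10)
  expect_equal(update_weights(c(0.01, 0.5), ew2), c(10, 2))
  gw <- weight_constraint("group", groups = c(1, 1), gamma = 0.5)
  w <- update_weights(c(0.5, 0.3), gw)
  expect_equal(w, rep(0.4^-0.5, 2), tolerance = 1e-10)
  # group closed form minimizes the joint objective (numeric check)
  f <- function(wv) wv * (0.5 + 0.3) - 2 * log(penalty_h(wv, 0.5))
  expect_equal(w[1], optimize(f, c(1e-6, 1e4), tol = 1e-12)$minimum,
               tolerance = 1e-5)
  gw2 <- weight_constraint("group", groups = c("A", "A", "B"))
  expect_equal(update_weights(c(0.5, 0.3, 0), gw2)[3], 1e5)
  expect_error(update_weights(c(1, 2), weight_constraint("group", groups = 1)),
               "every feature")
})

test_that("noiseless rank-1 data is recovered exactly at zero penalty", {
  b_star <- unitize(c(1, 1, -2, rep(0, 17)))   # zero-sum
  a_star <- unitize(c(2, -1, rep(0, 13)))
  d <- rank1_data(40, a_star, b_star, seed = 2)
  fit <- fit_cscca(d$Y, d$Z, solver_options(0, 0))
  expect_lt(sign_aligned_dist(fit$b, b_star), 1e-6)
  expect_lt(sign_aligned_dist(fit$a, a_star), 1e-6)
  expect_gte(abs(fit$sample_correlation), 0.999)
  expect_true(fit$converged)
  # unit norms, zero-sum, sign convention
  expect_equal(sqrt(sum(fit$a^2)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(fit$b^2)), 1, tolerance = 1e-8)
  expect_lt(abs(sum(fit$b)), 1e-6)
  expect_gt(fit$a[which.max(abs(fit$a))], 0)
})

test_that("an overwhelming penalty gives a degenerate pair with zero correlation", {
  b_star <- unitize(c(1, -1, rep(0, 8)))
  a_star <- unitize(c(1, rep(0, 7)))
  d <- rank1_data(30, a_star, b_star, seed = 4)
  fit <- fit_cscca(d$Y, d$Z, solver_options(0, 100))
  expect_true(fit$degenerate)
  expect_equal(fit$sample_correlation, 0)
  expect_equal(length(fit$support_b), 0L)
})

test_that("two-sided fits recover zero-sum directions on both sides", {
  a_star <- unitize(c(2, -1, -1, rep(0, 9)))    # zero-sum
  b_star <- unitize(c(1, 1, -2, rep(0, 12)))    # zero-sum
  d <- rank1_data(50, a_star, b_star, seed = 6)
  fit <- fit_cscca_two_sided(d$Y, d$Z, solver_options(0, 0))
  expect_lt(sign_aligned_dist(fit$a, a_star), 1e-6)
  expect_lt(sign_aligned_dist(fit$b, b_star), 1e-6)
  expect_lt(abs(sum(fit$a)), 1e-6)
  expect_lt(abs(sum(fit$b)), 1e-6)
  # symmetric inputs give symmetric directions
  withr::with_seed(8, U <- matrix(rnorm(200), 20, 10))
  fs <- fit_cscca_two_sided(U, U, solver_options(0, 0))
  expect_lt(sign_aligned_dist(fs$a, fs$b), 1e-5)
})

test_that("the unconstrained baseline is a thresholded power iteration", {
  withr::with_seed(10, {
    Y <- matrix(rnorm(200), 20, 10)
    Z <- matrix(rnorm(160), 20, 8)
  })
  fit <- fit_scca_baseline(Y, Z, solver_options(0, 0))
  sv <- svd(cross_covariance(Y, Z))
  expect_lt(sign_aligned_dist(fit$a, sv$u[, 1]), 1e-6)
  expect_lt(sign_aligned_dist(fit$b, sv$v[, 1]), 1e-6)
  # no zero-sum constraint: the coefficient sum is generically nonzero
  expect_gt(abs(sum(fit$b)), 1e-3)
  deg <- fit_scca_baseline(Y, Z, solver_options(0, 100))
  expect_true(deg$degenerate)
})

test_that("fitted directions are invariant to a positive rescaling of the covariance", {
  b_star <- unitize(c(1, 0.5, -1.5, rep(0, 7)))
  a_star <- unitize(c(1, -2, rep(0, 6)))
  d <- rank1_data(30, a_star, b_star, seed = 12)
  noise <- withr::with_seed(13, list(
    Y = matrix(rnorm(30 * 8, sd = 0.3), 30, 8),
    Z = matrix(rnorm(30 * 10, sd = 0.3), 30, 10)))
  Y <- d$Y + noise$Y; Z <- d$Z + noise$Z
  cfac <- 7
  f1 <- fit_cscca(Y, Z, solver_options(0.05, 0.05))
  f2 <- fit_cscca(cfac * Y, Z, solver_options(0.05 * cfac, 0.05 * cfac))
  expect_lt(sign_aligned_dist(f1$a, f2$a), 1e-5)
  expect_lt(sign_aligned_dist(f1$b, f2$b), 1e-5)
})

test_that("achieved correlation decreases with the compositional penalty", {
  b_star <- unitize(c(2, 1, -3, rep(0, 9)))
  a_star <- unitize(c(1, 1, rep(0, 6)))
  d <- rank1_data(40, a_star, b_star, seed = 14)
  lams <- c(0, 0.05, 0.1, 0.2, 0.4)
  cors <- sapply(lams, function(l)
    abs(suppressWarnings(fit_cscca(d$Y, d$Z, solver_options(0, l)))$sample_correlation))
  expect_true(all(diff(cors) <= 1e-8))
})

test_that("group-informed weights confine the support to the signal group", {
  # all signal in group 1 of 2; noiseless; after the first weight round the
  # other group's weights hit C_U, whose penalty exceeds any update entry
  b_star <- unitize(c(1, 1, -2, 0.5, -0.5, rep(0, 5)))  # zero-sum, group 1
  a_star <- unitize(c(1, -1, rep(0, 4)))
  d <- rank1_data(40, a_star, b_star, seed = 16)
  groups <- rep(1:2, each = 5)
  res <- fit_sacca(d$Y, d$Z, solver_options(0, 0.01),
                   weight_constraint("group", groups = groups, gamma = 0.5))
  expect_true(all(res$pair$support_b <= 5))
  expect_lt(sign_aligned_dist(res$pair$b, b_star), 0.05)
  expect_equal(res$weights[6:10], rep(1e5, 5))
})

test_that("adaptive weights keep an already-correct sparse solution stable", {
  b_star <- unitize(c(1.5, -1, -0.5, rep(0, 9)))
  a_star <- unitize(c(1, 0.5, rep(0, 5)))
  d <- rank1_data(40, a_star, b_star, seed = 18)
  res <- fit_sacca(d$Y, d$Z, solver_options(0.01, 0.01),
                   weight_constraint("elementwise_box", gamma = 0.5))
  expect_equal(sort(res$pair$support_b), 1:3)
  expect_equal(res$weights[4:12], rep(1e5, 9))
  expect_lt(sign_aligned_dist(res$pair$b, b_star), 0.05)
})

test_that("group weighting stays competitive when the structure is misspecified", {
  # S2-style signal split across groups containing zeros: the paired,
  # CV-tuned group-weighted runs should stay within 10% of the
  # elementwise-adaptive runs on the same datasets
  res <- run_experiment(setups = "S2", dims = list(c(20, 20)), sigma_nu = 4,
                        methods = c("accca", "sacca"), n_replicates = 3,
                        n = 100, n_groups = 4, seed = 60, nlam = 6)
  s <- res$summary
  mcc_sac <- s[s$method == "sacca" & s$metric == "MCC_b", "mean"]
  mcc_ada <- s[s$method == "accca" & s$metric == "MCC_b", "mean"]
  expect_gte(mcc_sac, 0.9 * mcc_ada)
})

test_that("a tuned compositional fit recovers the S2 signal support", {
  cfg <- simulation_config("S2", n = 200, p = 20, q = 20, sigma_nu = 8,
                           seed = 7, n_groups = 4)
  d <- simulate_dataset(cfg)
  lam_grid <- c(0.05, 0.1, 0.2, 0.4)
  supports <- lapply(lam_grid, function(l)
    fit_cscca(d$Y, d$logX, solver_options(0.1, l))$support_b)
  hits <- vapply(supports, function(s) all(c(1, 2, 3, 6, 7, 8) %in% s),
                 logical(1))
  expect_true(any(hits))
})

test_that("coefficient tables round-trip through the writer", {
  b_star <- unitize(c(1, -1, rep(0, 4)))
  a_star <- unitize(c(1, 1, 0, 0))
  d <- rank1_data(20, a_star, b_star, seed = 20)
  fit <- fit_cscca(d$Y, d$Z, solver_options(0, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_coefficients(fit, path, metadata_path = meta, seed = 3)
  df <- read_coefficients(path)
  expect_equal(df$coefficient[df$side == "a"], fit$a)
  expect_equal(df$coefficient[df$side == "b"], fit$b)
  expect_equal(jsonlite::read_json(meta)$seed, 3)
})
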