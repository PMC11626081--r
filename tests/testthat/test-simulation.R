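test_that("true loading vectors follow the printed patterns", {
  om <- make_omega("S1", 100, 100)
  expect_equal(sum(om$omega_X), 0)
  expect_equal(om$omega_X[10], 0.85 / 10 * -9)     # -0.765
  expect_equal(om$omega_X[1:9], rep(0.085, 9))
  expect_equal(which(om$omega_Y != 0), 1:10)
  expect_equal(om$omega_Y[1], 0.85 * 0.08)
  expect_equal(om$omega_Y[10], 0.85 * 0.12)
  # printed 3-decimal roundings of the evenly spaced ramp
  expect_equal(round(om$omega_Y[2:3] / 0.85, 3), c(0.084, 0.089))

  om2 <- make_omega("S2", 200, 200)
  expect_equal(which(om2$omega_X != 0), c(1, 2, 3, 6, 7, 8))
  expect_equal(sum(om2$omega_X), 0)
  expect_equal(om2$omega_X[8], 0.85 / 6 * -5)

  om3 <- make_omega("S3", 100, 100)
  expect_equal(sum(om3$omega_Y), 0, tolerance = 1e-12)  # 0.08..0.12 sums to 0.9
  expect_equal(om3$omega_Y[1:9], 0.85 * seq(0.08, 0.12, by = 0.005))
  expect_equal(om3$omega_Y[10], -0.85 * 0.9)

  om4 <- make_omega("S4", 100, 120)
  expect_equal(om4$omega_Y[1:10], om4$omega_X[1:10])
  expect_equal(sum(om4$omega_Y), 0)
  expect_error(make_omega("S1", 5, 100), "p, q >= 10")
})

test_that("group labels form contiguous equal-size blocks", {
  g <- make_groups(100, 20)
  expect_equal(as.integer(table(g)), rep(5L, 20))
  expect_equal(g[1:5], rep(1L, 5))
  expect_equal(make_groups(200, 20)[191:200], rep(20L, 10))
  expect_error(make_groups(50, 20), "divide")
})

test_that("the generator is seed-deterministic and leaves the caller's RNG alone", {
  cfg <- simulation_config("S2", n = 30, p = 20, q = 20, seed = 5)
  d1 <- simulate_dataset(cfg)
  set.seed(99); before <- rnorm(1)
  d2 <- simulate_dataset(cfg)
  set.seed(99); after <- rnorm(1)
  expect_identical(d1$logX, d2$logX)
  expect_identical(d1$Y, d2$Y)
  expect_equal(before, after)
  expect_equal(d1$truth$support_x, c(1, 2, 3, 6, 7, 8))
  expect_equal(sqrt(sum(d1$truth$target_x^2)), 1)
})

test_that("simulated moments match the latent-variable model", {
  cfg <- simulation_config("S1", n = 5000, p = 20, q = 20, sigma_nu = 4, seed = 8)
  d <- simulate_dataset(cfg)
  om <- make_omega("S1", 20, 20)
  v_emp <- apply(d$logX, 2, var)
  v_theo <- 16 * om$omega_X^2 + 1
  se <- sqrt(2 / (cfg$n - 1)) * v_theo   # sampling sd of a normal variance
  expect_true(all(abs(v_emp - v_theo) < 3.5 * se))
  # association strength: sample score correlation near the closed form
  nx <- sqrt(sum(om$omega_X^2)); ny <- sqrt(sum(om$omega_Y^2))
  rho <- 16 * nx * ny / sqrt((16 * nx^2 + 1) * (16 * ny^2 + 1))
  r_emp <- cor(d$logX %*% om$omega_X, d$Y %*% om$omega_Y)
  expect_equal(as.numeric(r_emp), rho, tolerance = 0.03)
})

test_that("a zero association strength gives independent tables", {
  cfg <- simulation_config("S1", n = 4000, p = 12, q = 12, sigma_nu = 0, seed = 9,
                           n_groups = 12)
  d <- simulate_dataset(cfg)
  expect_lt(max(abs(cross_covariance(d$Y, d$logX))), 0.08)
})

test_that("selection metrics reproduce the confusion-matrix formulas", {
  m <- selection_metrics(1:10, 1:10, 100)
  expect_equal(c(m$TPR, m$FPR, m$MCC, m$Precision), c(1, 0, 1, 1))
  m2 <- selection_metrics(c(1, 3), c(1, 2), 4)  # TP=FP=TN=FN=1
  expect_equal(m2$MCC, 0)
  m3 <- selection_metrics(1:10, c(1:8, 11, 12), 100)
  expect_equal(m3$TP, 8); expect_equal(m3$FP, 2)
  expect_equal(m3$TPR, 0.8)
  expect_equal(m3$FPR, 2 / 90)
  expect_equal(m3$Precision, 0.8)
  expect_equal(m3$MCC, (8 * 88 - 2 * 2) / sqrt(10 * 10 * 90 * 90))
  # empty selection conventions
  m4 <- selection_metrics(integer(0), 1:5, 50)
  expect_equal(c(m4$TPR, m4$FPR, m4$MCC, m4$Precision), c(0, 0, 0, 0))
  expect_error(selection_metrics(c(0, 3), 1:2, 10), "out of range")
})

test_that("selection metrics agree with an exhaustive recount on random supports", {
  withr::with_seed(55, {
    for (i in 1:25) {
      total <- sample(10:40, 1)
      est <- sample(total, sample(0:total, 1))
      tru <- sample(total, sample(1:total, 1))
      m <- selection_metrics(est, tru, total)
      flags_est <- seq_len(total) %in% est
      flags_tru <- seq_len(total) %in% tru
      expect_equal(m$TP, sum(flags_est & flags_tru))
      expect_equal(m$FP, sum(flags_est & !flags_tru))
      expect_equal(m$TN, sum(!flags_est & !flags_tru))
      expect_equal(m$FN, sum(!flags_est & flags_tru))
    }
  })
})

test_that("RMSE to target is sign-aligned and handles degenerate inputs", {
  om <- c(3, -4, 0, 0)
  t <- om / 5
  expect_equal(rmse_to_target(t, om), 0)
  expect_equal(rmse_to_target(-t, om), 0)
  expect_equal(rmse_to_target(c(1, 0), c(0, 2)), 1)
  expect_equal(rmse_to_target(rep(0, 4), om), sqrt(mean(t^2)))
  expect_error(rmse_to_target(c(1, 0), c(0, 0)), "nonzero")
})

test_that("the experiment runner emits all metrics for every method cell", {
  res <- run_experiment(setups = "S2", dims = list(c(20, 20)), sigma_nu = 4,
                        methods = c("scca", "cscca"), n_replicates = 2,
                        n = 50, seed = 3, nlam = 4)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$replicates), 4)
  metrics <- c("TPR_a", "FPR_a", "MCC_a", "Precision_a",
               "TPR_b", "FPR_b", "MCC_b", "Precision_b",
               "RMSE_a", "RMSE_b", "correlation")
  for (m in c("scca", "cscca")) {
    sub <- res$summary[res$summary$method == m, ]
    expect_setequal(sub$metric, metrics)
    expect_true(all(is.finite(sub$mean)))
  }
  # deterministic under the same seed
  res2 <- run_experiment(setups = "S2", dims = list(c(20, 20)), sigma_nu = 4,
                         methods = c("scca", "cscca"), n_replicates = 2,
                         n = 50, seed = 3, nlam = 4)
  expect_equal(res$replicates$MCC_b, res2$replicates$MCC_b)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_experiment(res, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(res$summary))
})
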