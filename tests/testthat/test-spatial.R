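test_that("spatial REML recovers zero autocorrelation on a large field", {
  sim <- make_small_trial(seed = 21L, n_lines = 400L, field = c(20L, 21L),
                          tps = c(150L, 200L), phi_c = 0, phi_r = 0)
  f <- fit_spatial_tp(sim$pheno, 150L)
  expect_lt(abs(f$phi_c), 0.1)
  expect_lt(abs(f$phi_r), 0.1)
})

test_that("null genetic variance is recovered as a small ratio", {
  grid <- tp_grid(c(150L, 200L))
  map <- simulate_map(1L, 3L, 50, seed = 1L)
  geno <- simulate_ril_genotypes(map, 380L, seed = 2L)
  truth <- trial_truth(grid$tps, lambda = 0, psi = 0, sigma2_xi = 0.004,
                       phi_c = 0.3, phi_r = 0.3, sigma2_eta = 0.004)
  sim <- simulate_trial(geno, map, grid, truth, field = c(20L, 20L),
                        n_check_plots = 20L, seed = 3L)
  f <- fit_spatial_tp(sim$pheno, 150L)
  expect_lt(f$sigma2_g / (f$sigma2_g + f$sigma2_xi + f$sigma2_eta), 0.05)
})

test_that("the fit is invariant to plot order and phenotype shifts", {
  sim <- make_small_trial(seed = 23L, n_lines = 60L, field = c(8L, 10L))
  f1 <- fit_spatial_tp(sim$pheno, 100L)
  shuf <- sim$pheno[sample.int(nrow(sim$pheno)), ]
  class(shuf) <- class(sim$pheno)
  f2 <- fit_spatial_tp(shuf, 100L)
  expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-5)
  expect_equal(f1$blup, f2$blup, tolerance = 1e-5)

  shifted <- sim$pheno
  shifted$value <- shifted$value + 5
  f3 <- fit_spatial_tp(shifted, 100L)
  h1 <- heritability(f1, se = FALSE)$H2
  h3 <- heritability(f3, se = FALSE)$H2
  expect_equal(h1, h3, tolerance = 1e-4)
  expect_equal(f3$mu - f1$mu, 5, tolerance = 1e-4)
})

test_that("heritability follows its definition and flags zero variance", {
  fake <- structure(list(sigma2_g = 1, sigma2_xi = 0.5, sigma2_eta = 0.5),
                    class = "spatial_fit")
  expect_equal(heritability(fake, se = FALSE)$H2, 0.5)
  fake0 <- structure(list(sigma2_g = 0, sigma2_xi = 0.3, sigma2_eta = 0.7),
                     class = "spatial_fit")
  expect_equal(heritability(fake0, se = FALSE)$H2, 0)
  none <- structure(list(sigma2_g = 0, sigma2_xi = 0, sigma2_eta = 0),
                    class = "spatial_fit")
  expect_error(heritability(none, se = FALSE), "zero total variance")
})

test_that("H2 estimates are approximately unbiased on repeated trials", {
  # scaled-down bias check: 12 replicate fields at plot-level H2 = 0.6
  h2s <- vapply(1:12, function(i) {
    sim <- make_small_trial(seed = 300L + i, n_lines = 100L,
                            field = c(10L, 12L), h2 = 0.6)
    heritability(fit_spatial_tp(sim$pheno, 100L), se = FALSE)$H2
  }, 0)
  expect_lt(abs(mean(h2s) - 0.6), 0.08)
})

test_that("FA(1) EM recovers known loadings and specific variances", {
  set.seed(31)
  nt <- 10L
  lam <- seq(0.5, 2, length.out = nt)
  psi <- rep(0.4, nt)
  Y <- outer(stats::rnorm(500), lam) +
    matrix(stats::rnorm(500 * nt), 500, nt) %*% diag(sqrt(psi))
  fa <- fit_fa1(Y)
  expect_lt(sqrt(mean((fa$lambda - lam)^2)) / mean(lam), 0.10)
  expect_true(all(fa$psi >= 0))
  expect_gte(fa$lambda[nt], 0)                 # sign convention
  # implied covariance is PSD and symmetric
  ev <- eigen(fa$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # one-factor model cannot fit worse than the diagonal model
  expect_gte(fa$loglik, fa$loglik_diag - 1e-6)
})

test_that("psi = 0 data give an effectively rank-1 correlation matrix", {
  set.seed(32)
  lam <- c(1, 2, 3, 4)
  Y <- outer(stats::rnorm(400), lam)
  fa <- suppressWarnings(fit_fa1(Y))
  R <- genetic_correlations(fa)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2L] / ev[1L], 0.05)
  expect_true(all(abs(R[upper.tri(R)]) > 0.99))
})

test_that("genetic correlations follow the FA(1) closed form", {
  # worked 3-TP case: lambda = (1,2,3), psi = (1,1,1)
  fa <- list(Sigma = tcrossprod(c(1, 2, 3)) + diag(3))
  R <- genetic_correlations(fa)
  expect_equal(R[1L, 3L], 3 / sqrt(2 * 10), tolerance = 1e-12)
  expect_equal(diag(R), rep(1, 3))
  # a zero loading disconnects its TP
  fa0 <- list(Sigma = tcrossprod(c(1, 0, 2)) + diag(c(1, 1, 1)))
  R0 <- genetic_correlations(fa0)
  expect_equal(R0[1L, 2L], 0)
  expect_equal(R0[2L, 3L], 0)
})

test_that("measurement-error-aware BLUPs shrink toward the mean", {
  set.seed(33)
  nt <- 4L
  Y <- matrix(stats::rnorm(300 * nt, sd = 1), 300, nt)
  fa <- fit_fa1(Y, error_var = rep(0.5, nt))
  Yc <- sweep(Y, 2L, colMeans(Y))
  # per-TP spread shrinks, and shrinkage preserves ranking
  expect_true(all(apply(fa$blup_matrix, 2L, stats::sd) <
                    apply(Yc, 2L, stats::sd)))
  for (t in seq_len(nt))
    expect_gt(stats::cor(fa$blup_matrix[, t], Yc[, t]), 0.95)
  # no error variance means no shrink
  fa0 <- fit_fa1(Y)
  expect_equal(fa0$blup_matrix, Yc, tolerance = 1e-9)
})

test_that("stage one assembles BLUPs, heritability and correlations", {
  sim <- make_small_trial(seed = 41L, n_lines = 80L, field = c(10L, 10L),
                          tps = c(100L, 150L, 200L))
  s1 <- stage_one_blups(sim$pheno)
  expect_equal(dim(s1$blup), c(80L, 3L))
  expect_equal(nrow(s1$heritability), 3L)
  expect_true(all(s1$heritability$H2 >= 0 & s1$heritability$H2 <= 1))
  expect_equal(dim(s1$gcor), c(3L, 3L))
  expect_equal(diag(s1$gcor), rep(1, 3L))
  # BLUPs track the simulated genetic values
  cors <- vapply(1:3, function(t)
    stats::cor(s1$blup[, t], sim$g[rownames(s1$blup), t]), 0)
  expect_true(all(cors > 0.5))
})

test_that("the per-TP significance table flags real genetic variance", {
  sim <- make_small_trial(seed = 42L, n_lines = 100L, field = c(10L, 12L),
                          tps = c(100L, 150L), h2 = 0.7)
  f <- fit_spatial_tp(sim$pheno, 100L)
  tab <- significance_table(list(f), alpha = 0.01)
  expect_true(tab$sig_g[1L])
  expect_gte(tab$lrt_g[1L], 0)
})
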