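test_that("map functions match their closed forms", {
  expect_equal(haldane_r(0), 0)
  expect_gt(haldane_r(10000), 0.499999)
  expect_equal(haldane_r(10), 0.5 * (1 - exp(-0.2)))   # 0.090634...
  expect_error(haldane_r(-1), "non-negative")

  expect_equal(ril_expansion(0), 0)
  expect_equal(ril_expansion(0.5), 0.5)                # fixed point
  r <- haldane_r(10)
  expect_equal(ril_expansion(r), 2 * r / (1 + 2 * r))  # 0.153449...
  expect_error(ril_expansion(0.6), "\\[0, 0.5\\]")
})

test_that("simulated maps are evenly spaced, validated and deterministic", {
  m <- simulate_map(1L, 11L, 100, seed = 3L)
  expect_equal(m$position, seq(0, 100, by = 10))
  big <- simulate_map(21L, 111L, 110, seed = 3L)
  expect_equal(nrow(big), 21L * 111L)                  # ~2330-marker scale
  expect_equal(simulate_map(3L, 5L, 50, seed = 9L),
               simulate_map(3L, 5L, 50, seed = 9L))
})

test_that("RIL genotypes have balanced alleles and map-consistent switches", {
  # effectively unlinked markers: 2 per chromosome, 10000 cM apart
  m <- simulate_map(100L, 2L, 10000, seed = 4L)
  g <- simulate_ril_genotypes(m, 2000L, seed = 5L)
  freq <- colMeans(g)
  se <- 0.5 / sqrt(2000)
  expect_true(all(abs(freq - 0.5) < 3 * se + 1e-12))

  # adjacent-marker switch fraction at d = 10 cM
  m2 <- simulate_map(1L, 2L, 10, seed = 4L)
  g2 <- simulate_ril_genotypes(m2, 5000L, seed = 6L)
  sw <- mean(g2[, 1L] != g2[, 2L])
  R <- ril_expansion(haldane_r(10))
  expect_lt(abs(sw - R), 3 * sqrt(R * (1 - R) / 5000))

  expect_identical(simulate_ril_genotypes(m2, 50L, seed = 7L),
                   simulate_ril_genotypes(m2, 50L, seed = 7L))
})

test_that("degenerate trial collapses to the mean curve", {
  grid <- tp_grid(c(100L, 150L, 200L))
  map <- simulate_map(1L, 5L, 50, seed = 1L)
  geno <- simulate_ril_genotypes(map, 20L, seed = 2L)
  truth <- trial_truth(grid$tps)          # all variance components zero
  sim <- simulate_trial(geno, map, grid, truth, field = c(5L, 5L),
                        n_check_plots = 0L, seed = 3L)
  mu <- growth_mean_curve(grid$tps)
  for (i in seq_along(grid$tps)) {
    vals <- sim$pheno$value[sim$pheno$tp == grid$tps[i]]
    expect_equal(vals, rep(mu[i], length(vals)))
  }
})

test_that("a persistent QTL shifts the two genotype classes by 2 alpha", {
  grid <- tp_grid(c(100L, 150L, 200L))
  map <- simulate_map(1L, 5L, 50, seed = 1L)
  geno <- simulate_ril_genotypes(map, 400L, seed = 2L)
  alpha <- 0.05
  truth <- trial_truth(grid$tps, qtls = list(
    list(chromosome = "C1", position = 25,
         effect = rep(alpha, 3L))), sigma2_eta = 1e-4)
  sim <- simulate_trial(geno, map, grid, truth, field = c(20L, 20L),
                        n_check_plots = 0L, seed = 3L)
  mk <- map$marker[which.min(abs(map$position - 25))]
  for (i in seq_along(grid$tps)) {
    d <- sim$pheno[sim$pheno$tp == grid$tps[i], ]
    cls <- geno[d$line, mk]
    contrast <- mean(d$value[cls == 1]) - mean(d$value[cls == 0])
    se <- sqrt(1e-4 * (1 / sum(cls == 1) + 1 / sum(cls == 0)))
    expect_lt(abs(contrast - 2 * alpha), 3 * se)
  }
})

test_that("simulated polygenic effects follow the FA(1) covariance", {
  grid <- tp_grid(c(100L, 130L, 160L, 190L, 220L))
  map <- simulate_map(1L, 3L, 50, seed = 1L)
  geno <- simulate_ril_genotypes(map, 800L, seed = 2L)
  lam <- c(0.02, 0.04, 0.06, 0.08, 0.10)
  psi <- rep(0.001, 5L)
  truth <- trial_truth(grid$tps, lambda = lam, psi = psi)
  sim <- simulate_trial(geno, map, grid, truth, field = c(29L, 28L),
                        n_check_plots = 0L, seed = 3L)
  g <- sim$g
  v_emp <- apply(g, 2L, stats::var)
  v_true <- lam^2 + psi
  expect_true(all(abs(v_emp / v_true - 1) < 0.25))
  # rank-1 temporal genetic correlation
  r_emp <- stats::cor(g[, 1L], g[, 5L])
  r_true <- lam[1L] * lam[5L] / sqrt(v_true[1L] * v_true[5L])
  expect_lt(abs(r_emp - r_true), 0.06)
})

test_that("spatial residual correlation decays as phi^lag along rows", {
  grid <- tp_grid(c(100L, 150L, 200L))
  map <- simulate_map(1L, 3L, 50, seed = 1L)
  geno <- simulate_ril_genotypes(map, 600L, seed = 2L)
  phi <- 0.6
  truth <- trial_truth(grid$tps, sigma2_xi = 1, phi_c = phi, phi_r = phi)
  sim <- simulate_trial(geno, map, grid, truth, field = c(25L, 24L),
                        n_check_plots = 0L, seed = 3L)
  d <- sim$pheno[sim$pheno$tp == 100L, ]
  d <- d[order(d$column, d$row), ]
  # lag-1 and lag-2 neighbours down each column of the field
  for (lag in 1:2) {
    same_col <- d$column[-seq_len(lag)] == d$column[seq_len(nrow(d) - lag)]
    x <- d$value[-seq_len(lag)][same_col]
    y <- d$value[seq_len(nrow(d) - lag)][same_col]
    expect_lt(abs(stats::cor(x, y) - phi^lag), 0.12)
  }
})

test_that("identical seeds reproduce the trial byte for byte", {
  a <- make_small_trial(seed = 11L)
  b <- make_small_trial(seed = 11L)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$g, b$g)
})

test_that("qtl_profile builds the three temporal archetypes", {
  grid <- tp_grid()
  pers <- qtl_profile(grid, "persistent", 0.1)
  expect_true(all(pers == 0.1))
  tra <- qtl_profile(grid, "transient", 0.1, at = 119L)
  expect_equal(sum(tra != 0), 1L)
  expect_equal(tra[match(119L, grid$tps)], 0.1)
  stg <- qtl_profile(grid, "stage", 0.1, at = "heading_flowering")
  expect_equal(sum(stg != 0), 4L)
})
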