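test_that("the VanRaden matrix matches hand arithmetic and its invariances", {
  g <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  K <- vanraden_g(g)
  # dosages [[0,2],[2,0]], p = 0.5: W = [[-1,1],[1,-1]], denom = 1
  expect_equal(K$denom, 1)
  expect_equal(unname(K$G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # identical lines have G_ij = G_ii
  g2 <- rbind(g, c = g["a", ])
  K2 <- vanraden_g(g2)
  expect_equal(K2$G["a", "c"], K2$G["a", "a"], tolerance = 1e-12)

  # marker order is irrelevant
  K3 <- vanraden_g(fx_geno)
  K4 <- vanraden_g(fx_geno[, sample.int(ncol(fx_geno))])
  expect_equal(K3$G, K4$G, tolerance = 1e-10)
  # inbred panel: mean diagonal near 1 + F = 2
  expect_lt(abs(mean(diag(K3$G)) - 2), 0.1)

  mono <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("m1", "m2")))
  expect_error(vanraden_g(mono), "monomorphic")
})

test_that("GBLUP equals ridge regression on markers at the same ratio", {
  set.seed(61)
  M <- matrix(stats::rbinom(20L * 50L, 1L, 0.5), 20, 50,
              dimnames = list(paste0("L", 1:20), paste0("m", 1:50)))
  K <- vanraden_g(M)
  y <- stats::rnorm(20)
  fit <- fit_gblup(y, K)
  dos <- 2 * M
  W <- sweep(dos, 2L, colMeans(dos))
  lam <- fit$sigma2_e / (fit$sigma2_a / K$denom)
  b <- solve(crossprod(W) + diag(lam, 50L), crossprod(W, y - fit$beta[1L]))
  expect_equal(unname(fit$gebv), unname(drop(W %*% b)), tolerance = 1e-6)
})

test_that("GEBVs are shift-invariant and h2g stays near zero under the null", {
  set.seed(62)
  K <- vanraden_g(fx_geno)
  y <- stats::rnorm(197)
  f1 <- fit_gblup(y, K)
  f2 <- fit_gblup(y + 100, K)
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-6)
  expect_equal(f2$beta[1L] - f1$beta[1L], 100, tolerance = 1e-6)
  expect_lt(f1$h2g, 0.15)
})

test_that("{0,1} and {0,2} dosage codings give identical GEBVs", {
  set.seed(63)
  y <- stats::rnorm(197, 0, 0.1) + 0.1 * fx_geno[, "C1_M010"]
  K2 <- vanraden_g(fx_geno)                  # {0,2} dosage internally
  # {0,1} coding: G proportional, scaled by its own denominator
  W1 <- sweep(fx_geno, 2L, colMeans(fx_geno))
  denom1 <- sum(colMeans(fx_geno) * (1 - colMeans(fx_geno)))
  G1 <- tcrossprod(W1) / denom1
  fa <- fit_gblup(y, K2)
  fb <- fit_gblup(y, G1)
  expect_equal(fa$gebv, fb$gebv, tolerance = 1e-5)
})

test_that("the MCMC backend agrees with REML on a strong-signal trait", {
  set.seed(64)
  K <- vanraden_g(fx_geno)
  L <- t(chol(K$G + diag(1e-8, 197L)))
  g <- drop(L %*% stats::rnorm(197L)) * 0.5
  y <- g + stats::rnorm(197L, 0, 0.3)
  fr <- fit_gblup(y, K)
  fm <- fit_gblup(y, K, method = "mcmc", n_iter = 3000L, burn_in = 1000L,
                  thin = 5L, seed = 2L)
  expect_gt(stats::cor(fr$gebv, fm$gebv), 0.98)
  expect_lt(abs(fr$h2g - fm$h2g), 0.15)
})

test_that("cross-validation tracks heritability and honours its defaults", {
  expect_equal(formals(cross_validate)$n_reps, 50L)
  expect_equal(formals(cross_validate)$train_frac, 0.75)
  set.seed(65)
  K <- vanraden_g(fx_geno)
  L <- t(chol(K$G + diag(1e-8, 197L)))
  g <- drop(L %*% stats::rnorm(197L))
  # a perfectly heritable trait is predicted almost perfectly
  cv_perfect <- cross_validate(cbind(perfect = g), K, n_reps = 10L,
                               seed = 1L)
  expect_gt(cv_perfect$summary$mean_r, 0.9)
  # predictive ability increases with heritability
  means <- vapply(c(0.2, 0.5, 0.8), function(h2) {
    y <- sqrt(h2) * g / stats::sd(g) +
      stats::rnorm(197L, 0, sqrt((1 - h2) * mean(diag(K$G))))
    cross_validate(cbind(t = y), K, n_reps = 15L, seed = 2L)$summary$mean_r
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("QTL fixed covariates do not hurt prediction of a major-gene trait", {
  set.seed(66)
  K <- vanraden_g(fx_geno)
  L <- t(chol(K$G + diag(1e-8, 197L)))
  poly <- drop(L %*% stats::rnorm(197L)); poly <- poly / stats::sd(poly)
  x <- 2 * fx_geno[, "C2_M025"] - 1
  y <- 0.8 * poly + 0.9 * x + stats::rnorm(197L, 0, 0.8)   # large QTL
  Y <- cbind(tp = y)
  sc <- fx_scores_of(make_null_blups(seed = 66L) + y)   # scores carry the QTL
  plain <- cross_validate(Y, K, n_reps = 10L, seed = 4L)
  with_q <- cross_validate(Y, K, n_reps = 10L, qtl_covariates = TRUE,
                           gp = fx_gp, pc_scores = sc$pcs$scores,
                           n_perm = 50L, seed = 4L)
  expect_gte(mean(with_q$replicates$r), mean(plain$replicates$r) - 0.01)
  expect_gt(max(with_q$replicates$n_qtl_covariates), 0L)
})

test_that("Fisher's Z transform behaves as atanh with clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))     # 0.54931...
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_warning(z <- fisher_z(1), "clamped")
  expect_true(is.finite(z))
})

test_that("Scott-Knott separates separated means and not null ones", {
  set.seed(67)
  # two clusters 10 pooled SDs apart -> exactly two groups
  gv <- list(s1 = stats::rnorm(50, 0, 0.1), s2 = stats::rnorm(50, 0, 0.1),
             s3 = stats::rnorm(50, 1, 0.1), s4 = stats::rnorm(50, 1, 0.1))
  grp <- scott_knott(gv)
  expect_equal(length(unique(grp)), 2L)
  expect_equal(unname(grp[c("s3", "s4")]), c("a", "a"))  # higher mean = "a"
  expect_equal(unname(grp[c("s1", "s2")]), c("b", "b"))

  # identical values collapse to one group
  same <- list(a = rep(1, 10), b = rep(1, 10), c = rep(1, 10))
  expect_equal(length(unique(scott_knott(same))), 1L)

  # null calibration (scaled down): one group in most runs
  one_group <- vapply(1:50, function(i) {
    set.seed(400L + i)
    gv0 <- lapply(1:4, function(j) stats::rnorm(30))
    names(gv0) <- paste0("s", 1:4)
    length(unique(scott_knott(gv0))) == 1L
  }, NA)
  expect_gte(mean(one_group), 0.8)
})
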