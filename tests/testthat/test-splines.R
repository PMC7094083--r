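test_that("noiseless cubic data select the smallest basis and fit exactly", {
  tps <- default_tps()
  Y <- t(vapply(1:20, function(i)
    1e-3 * i * tps + 2e-6 * tps^2 + 1e-9 * tps^3, numeric(length(tps))))
  sp <- fit_splines(Y, tps, seed = 1L)
  expect_equal(sp$n_basis, 4L)
  expect_lt(max(abs(curve_eval(sp, 3L, tps) - Y[3L, ])), 1e-8)
})

test_that("CV folds partition time points and the SSE matches brute force", {
  tps <- default_tps()
  set.seed(5)
  Y <- matrix(stats::rnorm(40 * length(tps)), 40)
  sp <- fit_splines(Y, tps, candidate_bases = c(4L, 6L, 8L), n_folds = 10L,
                    seed = 9L)
  # every TP held out exactly once, near-equal fold sizes
  expect_equal(sort(unique(sp$folds)), 1:10)
  expect_lte(diff(range(table(sp$folds))), 1L)

  # brute-force CV oracle for one candidate, reusing the returned folds
  K <- 6L
  kn <- c(rep(min(tps), 4L), seq(min(tps), max(tps),
                                 length.out = K - 2L)[-c(1L, K - 2L)],
          rep(max(tps), 4L))
  sse <- 0
  for (f in 1:10) {
    tr <- sp$folds != f
    Btr <- splines::splineDesign(kn, tps[tr], ord = 4L)
    Bte <- splines::splineDesign(kn, tps[!tr], ord = 4L)
    cf <- t(solve(crossprod(Btr), t(Y[, tr] %*% Btr)))
    sse <- sse + sum((Y[, !tr] - cf %*% t(Bte))^2)
  }
  expect_equal(unname(sp$cv_curve["6"]), sse, tolerance = 1e-8)

  # pure-noise data: the CV curve does not reward bigger bases
  expect_true(which.min(sp$cv_curve) == 1L)
})

test_that("oversized candidates are dropped with a warning", {
  tps <- c(10, 20, 30, 40, 50)
  Y <- matrix(stats::rnorm(10 * 5), 10)
  expect_warning(sp <- fit_splines(Y, tps, candidate_bases = c(4L, 9L),
                                   seed = 1L), "dropping")
  expect_equal(names(sp$cv_curve), "4")
})

test_that("curve evaluation matches an independent de Boor recursion", {
  tps <- default_tps()
  set.seed(6)
  Y <- matrix(stats::rnorm(5 * length(tps)), 5)
  sp <- fit_splines(Y, tps, candidate_bases = 7L, seed = 1L)

  deboor <- function(knots, deg, cf, x) {     # independent evaluator
    k <- findInterval(x, knots, rightmost.closed = TRUE)
    k <- min(max(k, deg + 1L), length(knots) - deg - 1L)
    d <- cf[(k - deg):k]
    for (r in 1:deg) for (j in deg:(r)) {
      i <- k - deg + j
      al <- (x - knots[i]) / (knots[i + deg - r + 1L] - knots[i])
      d[j + 1L] <- (1 - al) * d[j] + al * d[j + 1L]
    }
    d[deg + 1L]
  }
  for (x in c(30.5, 100, 217.3)) {
    expect_equal(curve_eval(sp, 2L, x),
                 deboor(sp$knots, 3L, sp$coef_matrix[2L, ], x),
                 tolerance = 1e-10)
  }
  # constant curves stay constant
  Yc <- matrix(1.5, 2, length(tps))
  spc <- fit_splines(Yc, tps, candidate_bases = 5L, seed = 1L)
  expect_equal(curve_eval(spc, 1L, c(50, 120, 200)), rep(1.5, 3L),
               tolerance = 1e-8)
  expect_error(curve_eval(sp, 1L, 500), "outside")
})

test_that("smoothing reduces noise relative to raw values", {
  tps <- default_tps()
  set.seed(7)
  truth <- t(vapply(1:60, function(i)
    growth_mean_curve(tps) * (0.8 + 0.01 * i), numeric(length(tps))))
  noisy <- truth + matrix(stats::rnorm(length(truth), 0, 0.05), nrow(truth))
  for (K in c(4L, 6L, 10L, 14L)) {
    sp <- fit_splines(noisy, tps, candidate_bases = K, seed = 1L)
    sm <- t(vapply(seq_len(nrow(noisy)), function(i)
      curve_eval(sp, i, tps), numeric(length(tps))))
    expect_lt(mean((sm - truth)^2), mean((noisy - truth)^2))
  }
})

test_that("functional PCA captures rank structure in the Gram metric", {
  tps <- default_tps()
  set.seed(8)
  base <- growth_mean_curve(tps)
  Y <- outer(stats::rnorm(50), base)           # rank-1 curves
  sp <- fit_splines(Y, tps, candidate_bases = 6L, seed = 1L)
  pcs <- functional_pca(sp, n_pc = 1L)
  expect_equal(pcs$varprop[1L], 1, tolerance = 1e-8)
  expect_lt(max(abs(colMeans(pcs$scores))), 1e-10)

  expect_equal(default_n_pc(5L), 3L)
  expect_equal(default_n_pc(10L), 4L)
  expect_equal(default_n_pc(26L), 5L)
  expect_error(functional_pca(sp, n_pc = 4L), "rank")
})

test_that("Gram-metric fPCA agrees with ordinary PCA on a fine grid", {
  tps <- default_tps()
  set.seed(9)
  Y <- make_null_blups(seed = 9L)
  sp <- fit_splines(Y, tps, candidate_bases = 7L, seed = 1L)
  pcs <- functional_pca(sp, n_pc = 3L)
  # evaluate smoothed curves on a fine grid and run plain PCA there
  fine <- seq(min(tps), max(tps), length.out = 400L)
  B <- splines::splineDesign(sp$knots, fine, ord = 4L)
  curves <- sp$coef_matrix %*% t(B)
  pv <- prcomp(curves)$sdev^2
  expect_equal(pcs$varprop[1:3], (pv / sum(pv))[1:3], tolerance = 0.01)
})

test_that("late spline coefficients track final height", {
  tps <- default_tps()
  set.seed(10)
  final <- stats::rnorm(80, 1, 0.1)
  Y <- t(vapply(final, function(h) growth_mean_curve(tps) * h,
                numeric(length(tps)))) +
    matrix(stats::rnorm(80 * length(tps), 0, 0.01), 80)
  sp <- fit_splines(Y, tps, candidate_bases = 8L, seed = 1L)
  for (j in c(sp$n_basis - 1L, sp$n_basis)) {
    expect_gt(stats::cor(sp$coef_matrix[, j], final, method = "spearman"),
              0.9)
  }
})
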