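#' Shared cubic B-spline basis over a time grid
#' @keywords internal
bspline_knots <- function(tps, n_basis) {
  t0 <- min(tps); t1 <- max(tps)
  n_interior <- n_basis - 4L
  interior <- if (n_interior > 0L)
    seq(t0, t1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric()
  c(rep(t0, 4L), interior, rep(t1, 4L))
}

#' @keywords internal
bspline_basis <- function(tps, n_basis) {
  splines::splineDesign(bspline_knots(tps, n_basis), tps, ord = 4L)
}

#' Smooth genotype trajectories with a cross-validated B-spline basis
#'
#' Fits one shared cubic B-spline basis (equispaced interior knots spanning
#' the observed DAS range) to every line's trajectory by least squares.  The
#' basis size is chosen from `candidate_bases` by k-fold cross-validation in
#' which the folds partition the *time points* (round-robin after a seeded
#' shuffle): the candidate minimising the held-out sum of squared errors,
#' summed over lines and folds, wins; ties go to the smaller basis.
#'
#' @param blups Lines x TPs matrix of adjusted genotypic values.
#' @param tps Numeric DAS vector (= `ncol(blups)`).
#' @param candidate_bases Candidate basis sizes (cubic, so >= 4).  Values
#'   exceeding the number of TPs are dropped with a warning.
#' @param n_folds Number of CV folds (capped at `length(tps)`).
#' @param seed Seed for the fold shuffle.
#' @return Object of class `"spline_fit"`: `n_basis`, `knots`,
#'   `coef_matrix` (lines x n_basis), `cv_curve` (named SSE per candidate),
#'   `tps`.
#' @export
fit_splines <- function(blups, tps, candidate_bases = 4:min(15L, length(tps)),
                        n_folds = 10L, seed = 1L) {
  blups <- as.matrix(blups)
  nt <- length(tps)
  stopifnot(ncol(blups) == nt, nt >= 5L)
  candidate_bases <- sort(unique(as.integer(candidate_bases)))
  if (any(candidate_bases < 4L)) stop("cubic basis needs n_basis >= 4")
  if (any(candidate_bases > nt)) {
    warning("dropping candidate basis sizes exceeding the number of TPs")
    candidate_bases <- candidate_bases[candidate_bases <= nt]
  }
  if (!length(candidate_bases)) stop("no usable candidate basis sizes")

  n_folds <- min(n_folds, nt)
  set.seed(seed)
  fold <- integer(nt)
  fold[sample.int(nt)] <- rep_len(seq_len(n_folds), nt)   # round-robin

  cv <- stats::setNames(numeric(length(candidate_bases)),
                        candidate_bases)
  for (ci in seq_along(candidate_bases)) {
    K <- candidate_bases[ci]
    sse <- 0
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      train <- fold != f
      Btr <- bspline_basis(tps, K)[train, , drop = FALSE]
      Bte <- bspline_basis(tps, K)[!train, , drop = FALSE]
      BtB <- crossprod(Btr)
      if (sum(train) < K || rcond_sym(BtB) < 1e-12) { ok <- FALSE; break }
      coefs <- blups[, train, drop = FALSE] %*% Btr %*% solve(BtB)
      pred <- coefs %*% t(Bte)
      sse <- sse + sum((blups[, !train, drop = FALSE] - pred)^2)
    }
    cv[ci] <- if (ok) sse else Inf
  }
  if (all(!is.finite(cv))) stop("no candidate basis size is estimable")
  # ties (to numerical precision) go to the smaller basis
  tol <- min(cv) + 1e-9 * (sum(blups^2) + 1)
  n_basis <- candidate_bases[which(cv <= tol)[1L]]

  B <- bspline_basis(tps, n_basis)
  coef_matrix <- blups %*% B %*% solve(crossprod(B))
  rownames(coef_matrix) <- rownames(blups)
  structure(list(n_basis = n_basis, knots = bspline_knots(tps, n_basis),
                 coef_matrix = coef_matrix, cv_curve = cv, tps = tps,
                 folds = fold),
            class = "spline_fit")
}

#' @keywords internal
rcond_sym <- function(A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) 0 else min(ev) / max(ev)
}

#' Evaluate a fitted spline curve
#'
#' @param fit A `spline_fit`.
#' @param line Line id (rowname of the coefficient matrix) or row index.
#' @param t DAS value(s) within the knot range (no extrapolation).
#' @return Evaluated height(s).
#' @export
curve_eval <- function(fit, line, t) {
  rng <- range(fit$knots)
  if (any(t < rng[1L] | t > rng[2L]))
    stop("evaluation outside the fitted DAS range [", rng[1L], ", ",
         rng[2L], "]")
  B <- splines::splineDesign(fit$knots, t, ord = 4L)
  drop(B %*% fit$coef_matrix[line, ])
}

#' Gram matrix of the B-spline basis
#'
#' Exact integrals `G_jk = int B_j(t) B_k(t) dt` over the knot span,
#' computed by 4-point Gauss-Legendre quadrature on each inter-knot
#' interval (exact for the degree-6 products of cubics).
#'
#' @param knots Full knot vector (as stored in a `spline_fit`).
#' @return n_basis x n_basis positive-definite matrix.
#' @export
bspline_gram <- function(knots) {
  brk <- unique(knots)
  K <- length(knots) - 4L
  # 4-point Gauss-Legendre nodes/weights on [-1, 1]
  gl_x <- c(-0.8611363115940526, -0.3399810435848563,
            0.3399810435848563, 0.8611363115940526)
  gl_w <- c(0.3478548451374538, 0.6521451548625461,
            0.6521451548625461, 0.3478548451374538)
  G <- matrix(0, K, K)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    x <- (a + b) / 2 + (b - a) / 2 * gl_x
    Bx <- splines::splineDesign(knots, x, ord = 4L)
    G <- G + crossprod(Bx * sqrt(gl_w * (b - a) / 2))
  }
  (G + t(G)) / 2
}

#' Functional principal component analysis of smoothed trajectories
#'
#' Eigen-decomposition of the between-line covariance of the B-spline
#' coefficients in the basis inner-product metric (the Gram matrix), i.e.
#' PCA of the curves as functions rather than of their coefficients.
#' Scores are centred; `varprop` comes from the eigenvalues.
#'
#' @param fit A `spline_fit`.
#' @param n_pc Number of components (default per the time-grid size:
#'   3, 4 or 5 components for 5, 10 or more TPs).
#' @return Object of class `"functional_pcs"`: `scores` (lines x n_pc,
#'   zero column means), `varprop`, `harmonics` (basis-coefficient
#'   loadings of each component) and `values` (all eigenvalues).
#' @export
functional_pca <- function(fit, n_pc = default_n_pc(length(fit$tps))) {
  n_pc_defaulted <- missing(n_pc)
  C <- fit$coef_matrix
  Cc <- sweep(C, 2L, colMeans(C))
  G <- bspline_gram(fit$knots)
  eg <- eigen(G, symmetric = TRUE)
  Ghalf <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Ghalf_inv <- eg$vectors %*% (1 / sqrt(pmax(eg$values, 1e-300)) * t(eg$vectors))
  S <- crossprod(Cc) / (nrow(Cc) - 1L)
  M <- Ghalf %*% S %*% Ghalf
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  rank <- sum(em$values > max(em$values, 0) * 1e-10)
  if (n_pc_defaulted) n_pc <- min(n_pc, fit$n_basis, rank)
  if (n_pc > rank) stop("n_pc = ", n_pc, " exceeds the rank (", rank, ")")
  scores <- Cc %*% Ghalf %*% em$vectors[, seq_len(n_pc), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  varprop <- em$values[seq_len(n_pc)] / sum(pmax(em$values, 0))
  harmonics <- Ghalf_inv %*% em$vectors[, seq_len(n_pc), drop = FALSE]
  structure(list(scores = scores, varprop = varprop, harmonics = harmonics,
                 values = em$values),
            class = "functional_pcs")
}

#' Default number of functional PCs for a time-grid size
#'
#' Three, four and five components for 5, 10 and 26 time points
#' respectively (linear interpolation rule: 3 for <= 5, 4 for <= 10,
#' 5 otherwise).
#' @param n_tps Number of time points.
#' @return Integer number of components.
#' @export
default_n_pc <- function(n_tps) {
  if (n_tps <= 5L) 3L else if (n_tps <= 10L) 4L else 5L
}
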