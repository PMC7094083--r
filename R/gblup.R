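#' VanRaden additive genomic relationship matrix
#'
#' First VanRaden formula `G = W W' / (2 sum p_j (1 - p_j))` with dosage
#' coding `{0, 2}` for the two homozygote classes and `W = dosage - 2 p_j`.
#' Monomorphic markers contribute nothing and are excluded from the
#' denominator.  For a fully inbred panel the diagonal is inflated to ~2,
#' which is the expected `1 + F` behaviour of this scaling.
#'
#' @param geno Lines x markers matrix in `{0,1}` (class 1 gets dosage 2).
#' @return List of class `"kinship"` with `G` (lines x lines) and `denom`.
#' @export
vanraden_g <- function(geno) {
  dos <- 2 * as.matrix(geno)
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("zero denominator: all markers monomorphic")
  W <- sweep(dos[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(W) / denom
  structure(list(G = G, denom = denom), class = "kinship")
}

#' Fit a GBLUP model by REML (spectral method)
#'
#' Single-random-effect model `y = X beta + a + e` with
#' `a ~ N(0, sigma2_a G)` and `e ~ N(0, sigma2_e I)`, fitted by REML after
#' rotating into the eigenbasis of `G`, where the likelihood is a cheap
#' one-dimensional profile in the variance ratio.  An MCMC (Gibbs) backend
#' is available behind `method = "mcmc"` with scaled-inverse-chi-squared
#' priors; its defaults follow common practice for this model class
#' (60000 iterations, 15000 burn-in, thin 5).
#'
#' @param y Phenotype vector (training lines).
#' @param K A `kinship` (or bare relationship matrix) covering at least
#'   the training lines; GEBVs are returned for every line in `K` by
#'   kinship projection.
#' @param fixed_covariates Optional covariate matrix for the training
#'   lines (intercept added automatically).
#' @param train Indices (or names) of `K`'s lines that `y` refers to;
#'   default all.
#' @param method `"reml"` (default) or `"mcmc"`.
#' @param n_iter,burn_in,thin MCMC settings (ignored for REML).
#' @param seed Seed for the MCMC backend.
#' @return Object of class `"gblup_fit"`: `sigma2_a`, `sigma2_e`, `h2g`,
#'   `beta`, `gebv` (all lines of `K`), `loglik`.
#' @export
fit_gblup <- function(y, K, fixed_covariates = NULL, train = NULL,
                      method = c("reml", "mcmc"), n_iter = 60000L,
                      burn_in = 15000L, thin = 5L, seed = 1L) {
  method <- match.arg(method)
  G <- if (inherits(K, "kinship")) K$G else as.matrix(K)
  n_all <- nrow(G)
  if (is.null(train)) train <- seq_len(n_all)
  if (is.character(train)) train <- match(train, rownames(G))
  Gt <- G[train, train, drop = FALSE]
  n <- length(y)
  stopifnot(n == length(train))
  X <- cbind(rep(1, n), fixed_covariates)
  p <- ncol(X)

  eg <- eigen((Gt + t(Gt)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(d))
    warning("kinship not PSD; negative eigenvalues clamped")
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  # profiled REML deviance in log variance ratio gamma = sigma2_a/sigma2_e
  dev <- function(lg) {
    gam <- exp(lg)
    w <- gam * d + 1
    XtWX <- crossprod(Xs, Xs / w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys / w)))
    r <- ys - Xs %*% beta
    ypy <- sum(r^2 / w)
    sum(log(w)) + 2 * sum(log(diag(ch))) + (n - p) * log(ypy)
  }

  if (method == "reml") {
    o <- stats::optimize(dev, c(-12, 12))
    # guard the boundaries
    if (dev(-12) < o$objective) o <- list(minimum = -12, objective = dev(-12))
    if (dev(12) < o$objective) o <- list(minimum = 12, objective = dev(12))
    gam <- exp(o$minimum)
    w <- gam * d + 1
    XtWX <- crossprod(Xs, Xs / w)
    beta <- solve(XtWX, crossprod(Xs, ys / w))
    r <- ys - Xs %*% beta
    sigma2_e <- sum(r^2 / w) / (n - p)
    sigma2_a <- gam * sigma2_e
    loglik <- -0.5 * (o$objective + (n - p) * (1 + log(2 * pi) -
                                                 log(n - p)))
  } else {
    fit <- gblup_gibbs(ys, Xs, d, n_iter, burn_in, thin, seed)
    sigma2_a <- fit$sigma2_a; sigma2_e <- fit$sigma2_e
    beta <- fit$beta
    gam <- sigma2_a / sigma2_e
    w <- gam * d + 1
    r <- ys - Xs %*% beta
    loglik <- NA_real_
  }

  # BLUP of a for all lines by kinship projection:
  # a_hat = sigma2_a G[, train] V^{-1} (y - X beta), V = sigma2_a Gt +
  # sigma2_e I; in the rotated space V^{-1} r = U (r_s / (sigma2_e w))
  vinv_r <- U %*% (r / (sigma2_e * w))
  gebv <- drop(sigma2_a * G[, train, drop = FALSE] %*% vinv_r)
  names(gebv) <- rownames(G)
  h2g <- if (sigma2_a + sigma2_e > 0) sigma2_a / (sigma2_a + sigma2_e) else 0
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e, h2g = h2g,
                 beta = drop(beta), gebv = gebv, loglik = loglik,
                 method = method),
            class = "gblup_fit")
}

# Gibbs sampler for the rotated GBLUP model
#' @keywords internal
gblup_gibbs <- function(ys, Xs, d, n_iter, burn_in, thin, seed) {
  set.seed(seed)
  n <- length(ys); p <- ncol(Xs)
  pos <- d > 1e-10
  s2a <- s2e <- stats::var(drop(ys)) / 2
  beta <- rep(0, p); u <- rep(0, n)
  nu <- 4; Sa <- Se <- s2a * (nu - 2) / nu
  keep_a <- keep_e <- numeric(); keep_b <- NULL
  XtX <- crossprod(Xs)
  for (it in seq_len(n_iter)) {
    # beta | rest
    Vb <- solve(XtX / s2e + diag(1e-8, p))
    mb <- Vb %*% (crossprod(Xs, ys - u) / s2e)
    beta <- drop(mb + t(chol(Vb)) %*% stats::rnorm(p))
    # u | rest (diagonal in the rotated space)
    r <- ys - Xs %*% beta
    prec <- 1 / s2e + ifelse(pos, 1 / (s2a * pmax(d, 1e-10)), Inf)
    mu_u <- (r / s2e) / prec
    u <- ifelse(pos, mu_u + stats::rnorm(n) / sqrt(prec), 0)
    # variances | rest
    ssu <- sum(u[pos]^2 / d[pos])
    s2a <- (ssu + nu * Sa) / stats::rchisq(1L, sum(pos) + nu)
    sse <- sum((r - u)^2)
    s2e <- (sse + nu * Se) / stats::rchisq(1L, n + nu)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      keep_a <- c(keep_a, s2a); keep_e <- c(keep_e, s2e)
      keep_b <- rbind(keep_b, beta)
    }
  }
  list(sigma2_a = mean(keep_a), sigma2_e = mean(keep_e),
       beta = matrix(colMeans(keep_b), ncol = 1L))
}

#' Fisher's Z transform of a correlation
#' @param r Correlation(s); values at or beyond +/-1 are clamped with a
#'   warning.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    warning("|r| >= 1 clamped")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}
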