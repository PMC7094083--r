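#' Fit a rank-1 factor-analytic temporal covariance
#'
#' Maximum-likelihood fit of `Sigma = lambda lambda' + Psi` (one factor,
#' per-time-point specific variances) to a lines x TPs matrix of adjusted
#' genotypic values, by EM.  If per-TP measurement-error variances are
#' supplied (e.g. the mean prediction error variance of stage-one BLUPs),
#' the model becomes `y = g + e` with `Var(g) = Sigma` and `Var(e) =
#' diag(error_var)`: the factor model is fitted to the error-corrected
#' covariance and the returned `blup_matrix` holds the conditional
#' expectations `E[g | y]`, i.e. values shrunken under `Sigma`.
#'
#' @param Y Lines x TPs numeric matrix.
#' @param error_var Optional per-TP measurement-error variances.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return Object of class `"fa1_fit"`: `lambda`, `psi`, `Sigma`,
#'   `blup_matrix`, `mu` (per-TP means), `loglik` and `loglik_diag` (the
#'   nested diagonal-covariance model).
#' @export
fit_fa1 <- function(Y, error_var = NULL, max_iter = 2000L, tol = 1e-10) {
  Y <- as.matrix(Y)
  n <- nrow(Y); nt <- ncol(Y)
  if (nt < 3L) stop("need at least 3 time points")
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  S <- crossprod(Yc) / n
  D <- if (is.null(error_var)) rep(0, nt) else rep_len(error_var, nt)
  # error-corrected target covariance for the genetic part
  Sg <- S - diag(D, nt)
  v <- pmax(diag(Sg), 1e-8 * max(diag(S), 1e-12))
  diag(Sg) <- v

  ll_of <- function(lambda, psi) {
    # marginal covariance of the observations
    Sig_y <- tcrossprod(lambda) + diag(psi + D, nt)
    ch <- chol(Sig_y)
    -n / 2 * (2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S)) +
                nt * log(2 * pi))
  }

  # init: first principal component of Sg
  es <- eigen(Sg, symmetric = TRUE)
  lambda <- es$vectors[, 1L] * sqrt(max(es$values[1L], 1e-12))
  psi <- pmax(v - lambda^2, 0.1 * v)
  psi_floor <- 1e-6 * v
  ll_old <- -Inf
  heywood <- FALSE
  for (it in seq_len(max_iter)) {
    # EM on the marginal model y = lambda f + (specific + error)
    psi_tot <- psi + D
    Sig_inv_l <- {
      # Woodbury: (ll' + diag(psi_tot))^{-1} lambda
      w <- lambda / psi_tot
      w / (1 + sum(lambda * w))
    }
    beta <- Sig_inv_l                      # = Sigma_y^{-1} lambda
    Sb <- drop(S %*% beta)
    gam <- 1 - sum(lambda * beta) + sum(beta * Sb)
    lambda_new <- Sb / gam
    psi_new <- pmax(diag(S) - lambda_new * Sb - D, psi_floor)
    if (any(psi_new <= psi_floor + 1e-15)) heywood <- TRUE
    lambda <- lambda_new; psi <- psi_new
    if (it %% 25L == 0L) {
      ll <- ll_of(lambda, psi)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1))
        break
      ll_old <- ll
    }
  }
  if (heywood)
    warning("Heywood case: specific variance clamped at its floor")
  if (lambda[nt] < 0) lambda <- -lambda    # sign convention
  loglik <- ll_of(lambda, psi)
  loglik_diag <- {
    Sig_y <- diag(pmax(diag(S), 1e-12), nt)
    -n / 2 * (sum(log(diag(Sig_y))) + nt + nt * log(2 * pi))
  }
  if (loglik < loglik_diag) {              # EM safeguard: diagonal fallback
    lambda <- rep(0, nt)
    psi <- pmax(diag(S) - D, psi_floor)
    loglik <- ll_of(lambda, psi)
  }
  Sigma <- tcrossprod(lambda) + diag(psi, nt)
  # shrunken genotypic values: E[g | y] = Sigma (Sigma + D)^{-1} (y - mu)
  shrink <- solve(Sigma + diag(D, nt), Sigma)
  blup_matrix <- Yc %*% shrink
  dimnames(blup_matrix) <- dimnames(Y)
  structure(list(lambda = lambda, psi = psi, Sigma = Sigma,
                 error_var = D, mu = mu, blup_matrix = blup_matrix,
                 loglik = loglik, loglik_diag = loglik_diag,
                 heywood = heywood),
            class = "fa1_fit")
}

#' Genetic correlations between time points
#'
#' `r_g(s,t) = Sigma_st / sqrt(Sigma_ss Sigma_tt)` from the fitted rank-1
#' temporal covariance; unit diagonal.
#'
#' @param fa An `fa1_fit`.
#' @return TPs x TPs correlation matrix.
#' @export
genetic_correlations <- function(fa) {
  sd <- sqrt(pmax(diag(fa$Sigma), 0))
  R <- fa$Sigma / outer(sd, sd)
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}
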