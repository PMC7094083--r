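#' Fit the per-time-point spatial mixed model
#'
#' REML fit of `value = mu + check + g_line + xi + eta` for the plots of one
#' time point, where `g_line` is a random RIL effect (checks are fixed),
#' `xi` is spatially correlated error with separable AR1xAR1 covariance
#' `sigma2_xi * AR1(phi_c) x AR1(phi_r)` over field columns and rows, and
#' `eta` is an independent nugget.  The autocorrelations are screened on a
#' grid (ties broken toward 0) and the full parameter vector is then
#' polished by Nelder-Mead on the profiled REML criterion.
#'
#' @param pheno A `pheno_long`.
#' @param tp The DAS to fit.
#' @param phi_grid Screening grid for `(phi_c, phi_r)`.
#' @param maxit Nelder-Mead iteration cap for the polish.
#' @return An object of class `"spatial_fit"`: variance components
#'   (`sigma2_g`, `sigma2_xi`, `sigma2_eta`, `phi_c`, `phi_r`), fixed
#'   effects (`mu`, `check_effects`), per-line `blup`, mean prediction error
#'   variance `pev_mean`, REML `loglik`, and Wald/LRT-style summaries.
#' @export
fit_spatial_tp <- function(pheno, tp,
                           phi_grid = seq(-0.9, 0.9, by = 0.3),
                           maxit = 400L) {
  d <- pheno[pheno$tp == tp, , drop = FALSE]
  if (nrow(d) < 30L) stop("need at least 30 plots at tp ", tp)
  n <- nrow(d)

  lines_ril <- sort(unique(d$line[!d$is_check]))
  checks <- sort(unique(d$line[d$is_check]))
  Z <- outer(d$line, lines_ril, "==") * !d$is_check
  storage.mode(Z) <- "double"
  X <- cbind(intercept = rep(1, n))
  for (ck in checks) X <- cbind(X, as.numeric(d$line == ck & d$is_check))
  colnames(X) <- c("intercept", checks)
  y <- d$value

  dr <- abs(outer(d$row, d$row, "-"))
  dc <- abs(outer(d$column, d$column, "-"))
  ZZt <- tcrossprod(Z)
  p <- ncol(X)

  # profiled negative REML log-likelihood; theta = (log g-ratio,
  # log xi-ratio, atanh phi_c, atanh phi_r); nugget variance profiled out
  nll <- function(theta) {
    gam_g <- exp(min(theta[1L], 20)); gam_xi <- exp(min(theta[2L], 20))
    phic <- 0.99 * tanh(theta[3L]); phir <- 0.99 * tanh(theta[4L])
    C <- (phic^dc) * (phir^dr)
    V0 <- gam_g * ZZt + gam_xi * C
    diag(V0) <- diag(V0) + 1
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, Vi_X)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Vi_y)))
    ypy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
    if (ypy <= 0) return(1e10)
    0.5 * (logdetV + 2 * sum(log(diag(chx))) + (n - p) * log(ypy))
  }

  # grid screen (|phi| ties resolved toward 0 by evaluation order); values
  # are snapped to exact zero so the Nelder-Mead start never carries
  # floating-point dust, which would degenerate its initial simplex
  grid_phis <- round(phi_grid[order(abs(phi_grid))], 10)
  best <- NULL
  for (pc in grid_phis) for (pr in grid_phis) {
    th <- c(0, 0, atanh(pc), atanh(pr))
    v <- nll(th)
    if (is.null(best) || v < best$v - 1e-9) best <- list(th = th, v = v)
  }
  opt <- stats::optim(best$th, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
  # one restart with a fresh simplex guards premature NM convergence
  start2 <- opt$par
  start2[abs(start2) < 1e-8] <- 0
  opt2 <- stats::optim(start2, nll, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-9))
  if (opt2$value < opt$value) opt <- opt2
  if (opt$value >= 1e10)
    stop("spatial REML did not converge; best grid point phi = (",
         tanh(best$th[3L]), ", ", tanh(best$th[4L]), ")")
  # parsimony: with phi_c = phi_r = 0 the spatial term merges with the
  # nugget, leaving its three parameters unidentified; retain the spatial
  # component only when it is AIC-supported, otherwise report phi = 0
  # (ties broken toward zero)
  opt0 <- stats::optimize(function(lg) nll(c(lg, -20, 0, 0)), c(-12, 12))
  if (opt0$objective - opt$value <= 3) {
    opt <- list(par = c(opt0$minimum, -20, 0, 0), value = opt0$objective)
  }
  th <- opt$par
  gam_g <- exp(min(th[1L], 20)); gam_xi <- exp(min(th[2L], 20))
  phic <- 0.99 * tanh(th[3L]); phir <- 0.99 * tanh(th[4L])

  C <- (phic^dc) * (phir^dr)
  V0 <- gam_g * ZZt + gam_xi * C
  diag(V0) <- diag(V0) + 1
  ch <- chol(V0)
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  XtViX_inv <- solve(XtViX)
  beta <- XtViX_inv %*% crossprod(X, Vi %*% y)
  r <- y - X %*% beta
  Vi_r <- Vi %*% r
  sigma2 <- drop(crossprod(r, Vi_r)) / (n - p)     # nugget variance
  sigma2_g <- gam_g * sigma2
  sigma2_xi <- gam_xi * sigma2

  # P y = Vi r at beta-hat; BLUP g = sigma2_g Z' P y / sigma2... V uses
  # ratios: g_hat = gam_g * Z' Vi r (scale-free since V = sigma2 * V0)
  blup <- drop(gam_g * crossprod(Z, Vi_r))
  names(blup) <- lines_ril
  # prediction error variance of the BLUPs
  P <- Vi - (Vi %*% X) %*% XtViX_inv %*% crossprod(X, Vi)
  ZtPZ_diag <- colSums(Z * (P %*% Z))
  pev <- pmax(sigma2_g - sigma2_g^2 / sigma2 * ZtPZ_diag, 0)

  loglik <- -(opt$value + 0.5 * (n - p) * (1 + log(2 * pi) - log(n - p)))

  # full 5-parameter negative REML loglik, for the information matrix
  nll5 <- function(par) {
    s2g <- exp(par[1L]); s2xi <- exp(par[2L]); s2eta <- exp(par[3L])
    pc <- 0.99 * tanh(par[4L]); pr <- 0.99 * tanh(par[5L])
    Cm <- (pc^dc) * (pr^dr)
    V <- s2g * ZZt + s2xi * Cm
    diag(V) <- diag(V) + s2eta
    chv <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(chv)) return(1e10)
    Vi_X <- backsolve(chv, forwardsolve(t(chv), X))
    Vi_y <- backsolve(chv, forwardsolve(t(chv), y))
    XtViX <- crossprod(X, Vi_X)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(1e10)
    bb <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Vi_y)))
    ypy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * bb)
    0.5 * (2 * sum(log(diag(chv))) + 2 * sum(log(diag(chx))) + ypy)
  }
  par5 <- c(log(max(sigma2_g, 1e-12)), log(max(sigma2_xi, 1e-12)),
            log(sigma2), atanh(phic / 0.99), atanh(phir / 0.99))

  structure(list(tp = tp, mu = beta[1L],
                 check_effects = stats::setNames(beta[-1L], checks),
                 sigma2_g = sigma2_g, sigma2_xi = sigma2_xi,
                 sigma2_eta = sigma2, phi_c = phic, phi_r = phir,
                 blup = blup, pev = pev, pev_mean = mean(pev),
                 loglik = loglik, n_plots = n, nll5 = nll5, par5 = par5),
            class = "spatial_fit")
}

#' Broad-sense heritability from a spatial fit
#'
#' Entry-mean heritability `H2 = sigma2_g / (sigma2_g + sigma2_eps)` with
#' `sigma2_eps = sigma2_xi + sigma2_eta`, and a delta-method standard error
#' from the numerically evaluated REML information matrix.
#'
#' @param fit A `spatial_fit`.
#' @param se Compute the delta-method standard error? (costs a 5x5 numeric
#'   Hessian of the REML criterion)
#' @return List with `H2` and `se` (`NA` if `se = FALSE`).
#' @export
heritability <- function(fit, se = TRUE) {
  tot <- fit$sigma2_g + fit$sigma2_xi + fit$sigma2_eta
  if (tot <= 0) stop("zero total variance")
  H2 <- fit$sigma2_g / tot
  se_val <- NA_real_
  if (se) {
    H <- num_hessian(fit$nll5, fit$par5)
    Sig <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Sig)) {
      # gradient of H2 wrt (log s2g, log s2xi, log s2eta)
      v <- c(fit$sigma2_g, fit$sigma2_xi, fit$sigma2_eta)
      gr <- c(v[1L] * (tot - v[1L]), -v[1L] * v[2L], -v[1L] * v[3L]) / tot^2
      gr5 <- c(gr, 0, 0)
      var_h2 <- drop(t(gr5) %*% Sig %*% gr5)
      if (is.finite(var_h2) && var_h2 >= 0) se_val <- sqrt(var_h2)
    }
  }
  list(H2 = H2, se = se_val)
}

# central-difference Hessian
#' @keywords internal
num_hessian <- function(f, x, h = 1e-3) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Per-time-point significance summary
#'
#' Likelihood-ratio test of the genetic variance (boundary-corrected
#' 0.5 chi-squared mixture) and Wald tests of the fixed effects, reported at
#' the given level for each fitted time point.
#'
#' @param fits List of `spatial_fit` objects.
#' @param alpha Significance level (default 0.01).
#' @return Data frame with one row per time point.
#' @export
significance_table <- function(fits, alpha = 0.01) {
  rows <- lapply(fits, function(f) {
    # LRT for sigma2_g: refit with the genetic component clamped near 0
    nll_full <- f$nll5(f$par5)
    par0 <- f$par5; par0[1L] <- log(1e-12)
    o0 <- stats::optim(par0[-1L], function(p) f$nll5(c(log(1e-12), p)),
                       method = "Nelder-Mead",
                       control = list(maxit = 200L))
    lrt <- max(0, 2 * (o0$value - nll_full))
    p_g <- 0.5 * stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
    data.frame(tp = f$tp, sigma2_g = f$sigma2_g, lrt_g = lrt, p_g = p_g,
               sig_g = p_g < alpha)
  })
  do.call(rbind, rows)
}

#' Stage-one BLUP extraction across all time points
#'
#' Runs [fit_spatial_tp()] for every time point, assembles the lines x TPs
#' BLUP matrix, fits the rank-1 factor-analytic temporal model to it (with
#' the per-TP mean prediction error variance as the measurement-error
#' variance), and reports heritabilities and genetic correlations.
#'
#' @param pheno A `pheno_long`.
#' @param tps Time points to fit (default: all present).
#' @param se Compute heritability standard errors?
#' @param ... Passed to [fit_spatial_tp()].
#' @return List of class `"stage_one"` with `fits`, `blup` (lines x TPs),
#'   `fa` (an `fa1_fit`), `heritability` (data frame) and `gcor`.
#' @export
stage_one_blups <- function(pheno, tps = sort(unique(pheno$tp)), se = FALSE,
                            ...) {
  fits <- lapply(tps, function(tp) fit_spatial_tp(pheno, tp, ...))
  lines_all <- sort(Reduce(intersect, lapply(fits, function(f) names(f$blup))))
  blup <- sapply(fits, function(f) f$blup[lines_all])
  dimnames(blup) <- list(lines_all, tps)
  err_var <- vapply(fits, function(f) f$pev_mean, 0)
  fa <- fit_fa1(blup, error_var = err_var)
  h2 <- do.call(rbind, lapply(fits, function(f) {
    h <- heritability(f, se = se)
    data.frame(tp = f$tp, H2 = h$H2, se = h$se)
  }))
  structure(list(fits = fits, blup = blup, fa = fa, heritability = h2,
                 gcor = genetic_correlations(fa)),
            class = "stage_one")
}
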