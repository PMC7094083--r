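#' Haley-Knott LOD score for one phenotype at one position
#'
#' `LOD = (n/2) log10(RSS0 / RSS1)` where `RSS0` is the residual sum of
#' squares of the regression of `y` on the covariates (plus intercept) and
#' `RSS1` additionally includes the genotype-probability regressor `x`.
#'
#' @param y Phenotype vector (no missing values).
#' @param x Genotype-probability vector.
#' @param covariates Optional covariate matrix.
#' @param cap LOD ceiling applied when `RSS1` underflows to zero.
#' @return The LOD score (>= 0 up to numerical round-off).
#' @export
hk_lod <- function(y, x, covariates = NULL, cap = 300) {
  if (anyNA(y)) stop("missing phenotypes are not allowed")
  n <- length(y)
  X0 <- cbind(rep(1, n), covariates)
  q0 <- qr(X0)
  r0 <- qr.resid(q0, y)
  rss0 <- sum(r0^2)
  if (rss0 <= max(1e-300, 1e-20 * sum(y^2))) return(0)  # constant phenotype
  r1 <- qr.resid(qr(cbind(X0, x)), y)
  rss1 <- sum(r1^2)
  if (rss1 <= 1e-300) return(structure(cap, capped = TRUE))
  max(0, n / 2 * log10(rss0 / rss1))
}

# Vectorised per-trait LOD curves: residualise Y and the probability matrix
# against the covariates (Frisch-Waugh), then use the rank-1 RSS update.
# Returns positions x traits LOD matrix.
#' @keywords internal
lod_curves <- function(Y, P, covariates = NULL) {
  n <- nrow(Y)
  X0 <- cbind(rep(1, n), covariates)
  q0 <- qr(X0)
  Yr <- qr.resid(q0, Y)
  Pr <- qr.resid(q0, P)
  rss0 <- colSums(Yr^2)                        # per trait
  xss <- colSums(Pr^2)
  cross <- crossprod(Pr, Yr)                   # positions x traits
  rss1 <- sweep(-(cross^2) / pmax(xss, 1e-300), 2L, rss0, "+")
  rss1 <- pmax(rss1, 1e-300)
  lod <- n / 2 * log10(sweep(1 / rss1, 2L, rss0, "*"))
  lod[xss <= 1e-12, ] <- 0                     # monomorphic positions
  pmax(lod, 0)
}

# Multivariate HKLOD curve via the determinant rank-1 update.
#' @keywords internal
hklod_curve <- function(Y, P, covariates = NULL) {
  n <- nrow(Y)
  X0 <- cbind(rep(1, n), covariates)
  q0 <- qr(X0)
  Yr <- qr.resid(q0, Y)
  Pr <- qr.resid(q0, P)
  A <- crossprod(Yr)
  if (rcond_sym(A) < 1e-12) {                  # singular residual matrix
    diag(A) <- diag(A) + 1e-8 * sum(diag(A))
    attr(A, "ridged") <- TRUE
  }
  Ainv <- solve(A)
  xnorm <- sqrt(pmax(colSums(Pr^2), 1e-300))
  U <- crossprod(Yr, sweep(Pr, 2L, xnorm, "/")) # traits x positions
  q <- as.numeric(colSums((Ainv %*% U) * U))
  q <- pmin(q, 1 - 1e-12)
  lod <- -n / 2 * log10(1 - q)
  lod[colSums(Pr^2) <= 1e-12] <- 0
  pmax(lod, 0)
}

#' Individual-time-point genome scan (IM / CIM)
#'
#' Interval mapping is Haley-Knott regression of each time point's adjusted
#' values on the genotype probability at every grid position.  Composite
#' interval mapping adds `n_covar` forward-selected typed-marker covariates
#' (refreshed per time point); covariates within `window` cM of the test
#' position are dropped while that position is tested.
#'
#' @param blups Lines x TPs matrix.
#' @param gp A `geno_probs` for the same lines.
#' @param mode `"IM"` or `"CIM"`.
#' @param n_covar Number of CIM marker covariates (default 5).
#' @param window Exclusion window around the test position in cM
#'   (default 10).
#' @return List of class `"scan_set"`: `lod` (positions x TPs matrix),
#'   `positions`, `mode`.
#' @export
scan_individual <- function(blups, gp, mode = c("IM", "CIM"), n_covar = 5L,
                            window = 10) {
  mode <- match.arg(mode)
  Y <- as.matrix(blups)
  P <- gp$probs
  if (mode == "IM" || n_covar == 0L) {
    lod <- lod_curves(Y, P)
  } else {
    typed <- which(!is.na(gp$positions$marker))
    n_covar <- min(n_covar, length(typed))
    lod <- matrix(0, ncol(P), ncol(Y))
    for (t in seq_len(ncol(Y))) {
      sel <- forward_select_markers(Y[, t], P[, typed, drop = FALSE], n_covar)
      sel_idx <- typed[sel]
      lod[, t] <- cim_curve(Y[, t], P, gp$positions, sel_idx, window)
    }
  }
  dimnames(lod) <- list(NULL, colnames(Y))
  structure(list(lod = lod, positions = gp$positions, mode = mode,
                 n_covar = if (mode == "CIM") n_covar else 0L,
                 window = window),
            class = "scan_set")
}

# forward selection of marker covariates by residual-SS decrease
#' @keywords internal
forward_select_markers <- function(y, M, k) {
  n <- length(y)
  sel <- integer()
  X <- cbind(rep(1, n))
  for (i in seq_len(k)) {
    q0 <- qr(X)
    yr <- qr.resid(q0, y)
    Mr <- qr.resid(q0, M)
    gain <- colSums(Mr * yr)^2 / pmax(colSums(Mr^2), 1e-300)
    gain[sel] <- -Inf
    j <- which.max(gain)
    if (!is.finite(gain[j]) || gain[j] <= 0) break
    sel <- c(sel, j)
    X <- cbind(X, M[, j])
  }
  sel
}

# CIM LOD curve for one trait: positions grouped by which covariates fall
# inside the exclusion window
#' @keywords internal
cim_curve <- function(y, P, positions, covar_idx, window) {
  npos <- nrow(positions)
  lod <- numeric(npos)
  if (!length(covar_idx)) return(lod_curves(cbind(y), P)[, 1L])
  # signature of dropped covariates for every test position
  drop_mat <- sapply(covar_idx, function(ci)
    positions$chromosome == positions$chromosome[ci] &
      abs(positions$position - positions$position[ci]) <= window)
  sig <- apply(drop_mat, 1L, function(z) paste(which(z), collapse = ","))
  for (s in unique(sig)) {
    at <- sig == s
    dropped <- if (nzchar(s)) as.integer(strsplit(s, ",")[[1L]]) else integer()
    active <- covar_idx[setdiff(seq_along(covar_idx), dropped)]
    covs <- if (length(active)) P[, active, drop = FALSE] else NULL
    lod[at] <- lod_curves(cbind(y), P[, at, drop = FALSE], covs)[, 1L]
  }
  lod
}

#' Functional genome scan (HKLOD, MLOD, SLOD)
#'
#' `HKLOD = (n/2) log10(|RSS0| / |RSS(lambda)|)`, the determinant-based
#' multivariate Haley-Knott statistic computed on functional PC scores;
#' `MLOD(lambda) = max_t LOD(t, lambda)` and `SLOD(lambda) = mean_t
#' LOD(t, lambda)` summarise the per-time-point LOD curves.
#'
#' @param Y For HKLOD, the lines x PC score matrix; for MLOD/SLOD, the
#'   lines x TPs matrix whose per-TP LOD curves are summarised.
#' @param gp A `geno_probs`.
#' @param statistic `"HKLOD"`, `"MLOD"` or `"SLOD"`.
#' @param covariates Optional fixed covariates.
#' @return List of class `"scan_result"`: `positions`, `lod` (vector),
#'   `statistic`, and (once [permutation_threshold()] and [find_peaks()]
#'   have been applied) `threshold` and `peaks`.
#' @export
scan_functional <- function(Y, gp, statistic = c("HKLOD", "MLOD", "SLOD"),
                            covariates = NULL) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(Y)
  lod <- switch(statistic,
    HKLOD = hklod_curve(Y, gp$probs, covariates),
    MLOD = apply(lod_curves(Y, gp$probs, covariates), 1L, max),
    SLOD = rowMeans(lod_curves(Y, gp$probs, covariates)))
  structure(list(positions = gp$positions, lod = lod, statistic = statistic,
                 threshold = NA_real_, peaks = NULL),
            class = "scan_result")
}

#' Pre-generated permutation index matrix
#'
#' One shared matrix of permuted line orders, so thresholds of different
#' statistics are computed on identical permutations and are therefore
#' comparable.
#'
#' @param n_lines Number of lines.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return `n_lines` x `n_perm` integer matrix of row orders.
#' @export
make_perms <- function(n_lines, n_perm, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) sample.int(n_lines),
         integer(n_lines))
}

#' Genome-wide permutation threshold
#'
#' Permutes the line labels of the phenotype block jointly (rows of the
#' multi-trait matrix move together), applies the scanner to each
#' permutation, and returns the empirical `(1 - alpha)` quantile of the
#' genome-wide maxima.
#'
#' @param scanner Closure taking a permuted phenotype matrix and returning
#'   the genome-wide maximum of the scan statistic.
#' @param Y Phenotype matrix whose rows are permuted.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Genome-wide type-I error level (default 0.05).
#' @param seed Integer seed (ignored when `perms` is given).
#' @param perms Optional pre-generated index matrix from [make_perms()].
#' @return The threshold, with the permutation maxima in attribute
#'   `"maxima"`.
#' @details The threshold is the `k`-th order statistic of the permutation
#'   maxima with `k = ceiling((1 - alpha) (n_perm + 1))`, so that declaring
#'   a scan significant when its genome-wide maximum *exceeds* the
#'   threshold is the exact-size permutation test (size
#'   `(n_perm + 1 - k)/(n_perm + 1)`, e.g. 10/201 at `alpha = 0.05` with
#'   200 permutations).
#' @export
permutation_threshold <- function(scanner, Y, n_perm = 1000L, alpha = 0.05,
                                  seed = 1L, perms = NULL) {
  Y <- as.matrix(Y)
  if (is.null(perms)) perms <- make_perms(nrow(Y), n_perm, seed)
  maxima <- vapply(seq_len(ncol(perms)), function(i)
    scanner(Y[perms[, i], , drop = FALSE]), 0)
  structure(perm_quantile(maxima, alpha), maxima = maxima)
}

#' Exact-size permutation threshold from a vector of scan maxima
#'
#' @param maxima Genome-wide scan maxima from the permutations.
#' @param alpha Target genome-wide level.
#' @return The order statistic such that "observed maximum > threshold" is
#'   an exact-size test (see [permutation_threshold()]).
#' @export
perm_quantile <- function(maxima, alpha = 0.05) {
  n <- length(maxima)
  k <- min(n, ceiling((1 - alpha) * (n + 1L)))
  sort(maxima, partial = k)[k]
}

#' Call peaks on a LOD curve
#'
#' Local maxima above the threshold, merged within `merge_cM` (keeping the
#' higher peak), each with a 1.5-LOD support interval.
#'
#' @param scan A `scan_result` (or list with `positions` and `lod`).
#' @param threshold Genome-wide significance threshold.
#' @param drop LOD drop defining the support interval (default 1.5).
#' @param merge_cM Peaks closer than this on one chromosome are merged
#'   (default 20).
#' @return Data frame with `chromosome`, `position`, `lod`, `ci_lo`,
#'   `ci_hi`; zero rows if nothing exceeds the threshold.
#' @export
find_peaks <- function(scan, threshold, drop = 1.5, merge_cM = 20) {
  pos <- scan$positions; lod <- scan$lod
  out <- list()
  for (chr in unique(pos$chromosome)) {
    at <- pos$chromosome == chr
    l <- lod[at]; p <- pos$position[at]
    if (max(l) < threshold) next
    peaks <- data.frame(position = p[which.max(l)], lod = max(l))
    # additional local maxima above threshold, outside merge range
    ord <- order(l, decreasing = TRUE)
    for (i in ord) {
      if (l[i] < threshold) break
      if (all(abs(p[i] - peaks$position) > merge_cM))
        peaks <- rbind(peaks, data.frame(position = p[i], lod = l[i]))
    }
    peaks <- peaks[order(peaks$position), , drop = FALSE]
    ci <- t(vapply(seq_len(nrow(peaks)), function(k) {
      i <- which(p == peaks$position[k])[1L]
      lo <- i; while (lo > 1L && l[lo] > peaks$lod[k] - drop) lo <- lo - 1L
      hi <- i; while (hi < length(l) && l[hi] > peaks$lod[k] - drop)
        hi <- hi + 1L
      c(p[lo], p[hi])
    }, numeric(2L)))
    out[[chr]] <- data.frame(chromosome = chr, position = peaks$position,
                             lod = peaks$lod, ci_lo = ci[, 1L],
                             ci_hi = ci[, 2L], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chromosome = character(), position = numeric(),
                      lod = numeric(), ci_lo = numeric(), ci_hi = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
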