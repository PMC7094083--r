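#' Allele-substitution effect for a target PVE
#'
#' Inverts the single-locus relation `PVE = 1 / (1 + 1/(c k^2 p(1-p)))`,
#' where `k` is the simulated effect in phenotypic-SD units, to give
#' `k = sqrt(PVE / ((1-PVE) c p(1-p)))` and `alpha = k * sd_blup`.  With
#' effects `-alpha / +alpha` assigned to the two homozygote classes the
#' variance contributed is `4 alpha^2 p(1-p)`, so the exact constant is
#' `c = 4`; `c = 1` corresponds to reading `k` as the full between-class
#' difference in SD units.  The default `"empirical"` mode calibrates
#' `alpha` by Monte-Carlo bisection so the realised sample PVE matches the
#' target, and is the reference behaviour.
#'
#' @param pve Target proportion of variance explained, in (0, 1).
#' @param p Allele frequency of one class, in (0, 1).
#' @param sd_blup Phenotypic standard deviation of the trait the effect is
#'   added to.
#' @param mode `"empirical"` (Monte-Carlo calibration), `"c4"` (exact
#'   closed form for +/- alpha assignment) or `"c1"` (printed-relation
#'   constant).
#' @param n_mc Monte-Carlo sample size for the empirical mode.
#' @param seed Seed for the empirical mode.
#' @return The effect `alpha` in trait units.
#' @export
effect_from_pve <- function(pve, p, sd_blup, mode = c("empirical", "c4",
                                                      "c1"),
                            n_mc = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(pve > 0, pve < 1)
  if (p <= 0 || p >= 1) stop("degenerate allele frequency")
  cc <- if (mode == "c1") 1 else 4
  k <- sqrt(pve / ((1 - pve) * cc * p * (1 - p)))
  alpha <- k * sd_blup
  if (mode == "empirical") {
    set.seed(seed)
    g <- stats::rbinom(n_mc, 1L, p)
    y <- stats::rnorm(n_mc, 0, sd_blup)
    realised_pve <- function(a) {
      yy <- y + ifelse(g == 1L, a, -a)
      x <- 2 * g - 1
      stats::cor(yy, x)^2
    }
    lo <- alpha / 4; hi <- alpha * 4
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (realised_pve(mid) < pve) lo <- mid else hi <- mid
    }
    alpha <- (lo + hi) / 2
  }
  alpha
}

#' Perturb adjusted phenotypes with a simulated QTL at a marker
#'
#' Adds `-alpha` / `+alpha` to the two homozygote classes of `marker`,
#' either at every time point (`persistent`) or at a single time point
#' (`transient`).  The input matrix is not modified.
#'
#' @param blups Lines x TPs matrix.
#' @param geno Genotype matrix in `{0,1}` with matching rownames.
#' @param marker Marker id or column index.
#' @param alpha Allele-substitution effect.
#' @param qtl_type `"persistent"` or `"transient"`.
#' @param tp For `transient`, the column index perturbed (default: drawn
#'   uniformly).
#' @return The perturbed matrix, with the perturbed column index in
#'   attribute `"tp"` for transient QTLs.
#' @export
perturb <- function(blups, geno, marker, alpha,
                    qtl_type = c("persistent", "transient"), tp = NULL) {
  qtl_type <- match.arg(qtl_type)
  g <- geno[rownames(blups), marker]
  if (length(unique(g)) < 2L) stop("monomorphic marker")
  shift <- ifelse(g == 1L, alpha, -alpha)
  out <- blups
  if (qtl_type == "persistent") {
    out <- out + shift
  } else {
    if (is.null(tp)) tp <- sample.int(ncol(blups), 1L)
    out[, tp] <- out[, tp] + shift
    attr(out, "tp") <- tp
  }
  out
}

#' Data-perturbation power study
#'
#' Estimates detection power for simulated persistent or transient QTLs.
#' Permutation thresholds are computed once on the unperturbed data and
#' reused.  In each iteration a marker is drawn uniformly (resampling
#' monomorphic draws), a QTL of the target PVE is added by [perturb()], the
#' genome is scanned with each statistic, and a detection is scored when
#' the genome-wide maximum exceeds the pre-computed threshold *and* the
#' peak lies on the simulated marker's chromosome.  For IM at transient
#' QTLs, detection is scored on the perturbed time point's scan.
#'
#' @param blups Lines x TPs matrix of adjusted values (unperturbed).
#' @param geno Genotype matrix in `{0,1}`.
#' @param gp A `geno_probs` for the same lines.
#' @param pcs Lines x PCs score matrix used by the HKLOD statistic.
#' @param pve_grid Target PVE values.
#' @param qtl_type `"persistent"` or `"transient"`.
#' @param statistics Subset of `c("IM", "HKLOD", "MLOD", "SLOD")`.
#' @param n_iter Iterations per PVE value.
#' @param n_perm Permutations for the thresholds.
#' @param alpha Genome-wide level (default 0.05).
#' @param effect_mode Passed to [effect_from_pve()].
#' @param seed Integer seed; all randomness flows from it.
#' @return Data frame of class `"power_result"` with `statistic`, `pve`,
#'   `power`, `mc_se`, `n_iter`; thresholds in attribute `"thresholds"`.
#' @export
run_power <- function(blups, geno, gp, pcs, pve_grid = c(0.1, 0.2, 0.3),
                      qtl_type = c("persistent", "transient"),
                      statistics = c("IM", "HKLOD", "MLOD", "SLOD"),
                      n_iter = 100L, n_perm = 200L, alpha = 0.05,
                      effect_mode = "empirical", projection = NULL,
                      seed = 1L) {
  qtl_type <- match.arg(qtl_type)
  if ("HKLOD" %in% statistics && is.null(projection))
    stop("HKLOD needs the TPs x PCs projection from score_projection()")
  Y <- as.matrix(blups)
  n <- nrow(Y); nt <- ncol(Y)
  pos_chr <- gp$positions$chromosome

  # thresholds on the unperturbed data, shared permutation indices
  perms <- make_perms(n, n_perm, seed)
  thr <- list()
  if ("IM" %in% statistics) {
    # per-TP thresholds, as in individual-TP analyses
    thr$IM <- vapply(seq_len(nt), function(t)
      permutation_threshold(function(Yp) max(lod_curves(Yp, gp$probs)),
                            Y[, t, drop = FALSE], alpha = alpha,
                            perms = perms), 0)
  }
  for (s in intersect(c("HKLOD", "MLOD", "SLOD"), statistics)) {
    Yin <- if (s == "HKLOD") pcs else Y
    thr[[s]] <- permutation_threshold(function(Yp)
      max(scan_functional(Yp, gp, s)$lod), Yin, alpha = alpha,
      perms = perms)
  }

  set.seed(seed + 1L)
  res <- list()
  for (pve in pve_grid) {
    hits <- stats::setNames(numeric(length(statistics)), statistics)
    for (it in seq_len(n_iter)) {
      repeat {
        mk <- sample.int(ncol(geno), 1L)
        p_freq <- mean(geno[, mk])
        if (p_freq > 0 && p_freq < 1) break
      }
      mk_chr <- gp$positions$chromosome[
        match(colnames(geno)[mk], gp$positions$marker)]
      tp_hit <- if (qtl_type == "transient") sample.int(nt, 1L) else NA
      sd_t <- if (qtl_type == "transient") stats::sd(Y[, tp_hit])
              else mean(apply(Y, 2L, stats::sd))
      a <- effect_from_pve(pve, p_freq, sd_t, mode = effect_mode,
                           seed = seed + it)
      Yp <- perturb(Y, geno, mk, a, qtl_type, tp = tp_hit)
      # HKLOD operates on PC scores; the smoothing + fPCA map is linear in
      # the per-TP values, so the perturbed scores are obtained by pushing
      # the perturbed matrix through the same projection.
      for (s in statistics) {
        if (s == "IM") {
          if (qtl_type == "transient") {
            lod <- lod_curves(Yp[, tp_hit, drop = FALSE], gp$probs)[, 1L]
            det <- max(lod) > thr$IM[tp_hit] &&
              pos_chr[which.max(lod)] == mk_chr
          } else {
            lodm <- lod_curves(Yp, gp$probs)
            det <- FALSE
            for (t in seq_len(nt)) {
              if (max(lodm[, t]) > thr$IM[t] &&
                  pos_chr[which.max(lodm[, t])] == mk_chr) {
                det <- TRUE; break
              }
            }
          }
        } else {
          Yin <- if (s == "HKLOD") project_scores(Yp, projection) else Yp
          sc <- scan_functional(Yin, gp, s)
          det <- max(sc$lod) > thr[[s]] &&
            pos_chr[which.max(sc$lod)] == mk_chr
        }
        hits[s] <- hits[s] + det
      }
    }
    pw <- hits / n_iter
    res[[length(res) + 1L]] <- data.frame(
      statistic = statistics, pve = pve, power = as.numeric(pw),
      mc_se = sqrt(pw * (1 - pw) / n_iter), n_iter = n_iter,
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  attr(out, "thresholds") <- thr
  class(out) <- c("power_result", "data.frame")
  out
}

#' Linear map from per-TP values to functional PC scores
#'
#' The smoothing + fPCA pipeline is linear in the per-TP values; this
#' returns the TPs x PCs matrix `M` with `scores = (Y - colMeans) B` ...
#' i.e. `M` such that perturbed scores are `scores(Y + Delta) = scores(Y)
#' + Delta M`.  Used to propagate data perturbations into PC scores
#' without refitting.
#'
#' @param fit A `spline_fit`.
#' @param pcs The `functional_pcs` from that fit.
#' @return TPs x PCs projection matrix.
#' @export
score_projection <- function(fit, pcs) {
  B <- bspline_basis(fit$tps, fit$n_basis)
  coef_map <- B %*% solve(crossprod(B))        # TPs x n_basis
  G <- bspline_gram(fit$knots)
  eg <- eigen(G, symmetric = TRUE)
  Ghalf <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  # scores = Cc Ghalf U; harmonics store Ghalf^{-1} U, so recover U
  U <- Ghalf %*% pcs$harmonics
  coef_map %*% Ghalf %*% U
}

#' @keywords internal
project_scores <- function(Y, projection) {
  Yc <- sweep(Y, 2L, colMeans(Y))
  Yc %*% projection
}
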