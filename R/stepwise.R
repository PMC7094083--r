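# joint model statistic for a set of QTL positions (columns of gp$probs)
#' @keywords internal
joint_model_lod <- function(Y, gp, qtl_idx, statistic) {
  n <- nrow(Y)
  X0 <- cbind(rep(1, n))
  X1 <- cbind(X0, gp$probs[, qtl_idx, drop = FALSE])
  if (statistic == "HKLOD") {
    R0 <- qr.resid(qr(X0), Y); R1 <- qr.resid(qr(X1), Y)
    A0 <- crossprod(R0); A1 <- crossprod(R1)
    d0 <- determinant(A0, logarithm = TRUE)$modulus
    d1 <- determinant(A1, logarithm = TRUE)$modulus
    max(0, n / 2 * (d0 - d1) / log(10))
  } else {
    rss0 <- colSums(qr.resid(qr(X0), Y)^2)
    rss1 <- pmax(colSums(qr.resid(qr(X1), Y)^2), 1e-300)
    lods <- pmax(n / 2 * log10(rss0 / rss1), 0)
    if (statistic == "MLOD") max(lods) else mean(lods)
  }
}

# scan for the best position to add, conditional on current QTLs
#' @keywords internal
best_addition <- function(Y, gp, qtl_idx, statistic, exclusion_cM = 10) {
  covs <- if (length(qtl_idx)) gp$probs[, qtl_idx, drop = FALSE] else NULL
  lod <- switch(statistic,
    HKLOD = hklod_curve(Y, gp$probs, covs),
    MLOD = apply(lod_curves(Y, gp$probs, covs), 1L, max),
    SLOD = rowMeans(lod_curves(Y, gp$probs, covs)))
  # keep new QTLs away from ones already in the model
  for (qi in qtl_idx) {
    near <- gp$positions$chromosome == gp$positions$chromosome[qi] &
      abs(gp$positions$position - gp$positions$position[qi]) <= exclusion_cM
    lod[near] <- -Inf
  }
  which.max(lod)
}

#' Stepwise multiple-QTL model search with penalized LOD
#'
#' Forward selection of up to `max_qtl` additive QTLs followed by backward
#' elimination to the null model, scoring every visited model by
#' `pLOD = LOD_joint - penalty * #QTLs` and returning the model with the
#' highest pLOD over the whole trajectory (the null model scores 0).  A
#' final within-chromosome refinement pass re-optimises each retained QTL
#' position with the others held fixed.
#'
#' @param Y Lines x traits matrix (functional PC scores for HKLOD, per-TP
#'   values for MLOD/SLOD).
#' @param gp A `geno_probs`.
#' @param statistic `"HKLOD"`, `"MLOD"` or `"SLOD"`.
#' @param penalty Main-effect penalty per QTL; use the alpha = 0.05
#'   permutation threshold of the corresponding single-QTL scan.
#' @param max_qtl Maximum model size (default 6).
#' @return Object of class `"multiple_qtl_model"`: `qtls` (data frame of
#'   chromosome/position), `plod`, `trajectory` (models visited with their
#'   pLOD), `statistic`.
#' @export
stepwise_multiple_qtl <- function(Y, gp, statistic = c("HKLOD", "MLOD",
                                                       "SLOD"),
                                  penalty, max_qtl = 6L) {
  statistic <- match.arg(statistic)
  stopifnot(penalty > 0)
  Y <- as.matrix(Y)
  trajectory <- list(list(qtl_idx = integer(), plod = 0))
  plod_of <- function(idx)
    if (!length(idx)) 0
    else joint_model_lod(Y, gp, idx, statistic) - penalty * length(idx)

  # forward
  idx <- integer()
  for (k in seq_len(max_qtl)) {
    j <- best_addition(Y, gp, idx, statistic)
    idx <- c(idx, j)
    trajectory[[length(trajectory) + 1L]] <-
      list(qtl_idx = idx, plod = plod_of(idx))
  }
  # backward from the full forward model
  bidx <- idx
  while (length(bidx) > 1L) {
    cand <- lapply(seq_along(bidx), function(i) bidx[-i])
    plods <- vapply(cand, plod_of, 0)
    bidx <- cand[[which.max(plods)]]
    trajectory[[length(trajectory) + 1L]] <-
      list(qtl_idx = bidx, plod = max(plods))
  }
  best <- trajectory[[which.max(vapply(trajectory, `[[`, 0, "plod"))]]
  idx <- best$qtl_idx

  # within-chromosome position refinement
  if (length(idx)) {
    for (pass in 1:3) {
      moved <- FALSE
      for (i in seq_along(idx)) {
        chr <- gp$positions$chromosome[idx[i]]
        on_chr <- which(gp$positions$chromosome == chr)
        others <- idx[-i]
        covs <- if (length(others)) gp$probs[, others, drop = FALSE] else NULL
        lod <- switch(statistic,
          HKLOD = hklod_curve(Y, gp$probs[, on_chr, drop = FALSE], covs),
          MLOD = apply(lod_curves(Y, gp$probs[, on_chr, drop = FALSE], covs),
                       1L, max),
          SLOD = rowMeans(lod_curves(Y, gp$probs[, on_chr, drop = FALSE],
                                     covs)))
        new <- on_chr[which.max(lod)]
        if (new != idx[i]) { idx[i] <- new; moved <- TRUE }
      }
      if (!moved) break
    }
  }
  qtls <- gp$positions[idx, c("chromosome", "position"), drop = FALSE]
  rownames(qtls) <- NULL
  structure(list(qtls = qtls, qtl_idx = idx, plod = plod_of(idx),
                 trajectory = trajectory, statistic = statistic,
                 penalty = penalty),
            class = "multiple_qtl_model")
}

#' Per-time-point QTL effects and variance explained
#'
#' For each time point, jointly regresses that time point's adjusted values
#' on the genotype probabilities of all model QTLs.  The reported effect is
#' the allele-substitution effect (half the fitted class difference; a
#' positive sign means the second-parent allele increases the trait) and
#' `pve` is `100 (RSS_drop - RSS_full) / TSS` for dropping the QTL from the
#' joint model.
#'
#' @param blups Lines x TPs matrix.
#' @param model A `multiple_qtl_model` (non-empty).
#' @param gp The `geno_probs` the model indexes into.
#' @return Data frame with `qtl`, `chromosome`, `position`, `tp`, `effect`,
#'   `pve`.  If the QTL probabilities are collinear, PVE falls back to
#'   sequential ANOVA in map order and the result carries attribute
#'   `"sequential" = TRUE`.
#' @export
qtl_effects <- function(blups, model, gp) {
  if (!length(model$qtl_idx)) stop("empty QTL model")
  Y <- as.matrix(blups)
  n <- nrow(Y)
  Xq <- gp$probs[, model$qtl_idx, drop = FALSE]
  X <- cbind(1, Xq)
  sequential <- rcond_sym(crossprod(X)) < 1e-10
  qx <- qr(X)
  Yc <- sweep(Y, 2L, colMeans(Y))
  tss <- colSums(Yc^2)
  rss_full <- colSums(qr.resid(qx, Y)^2)
  beta <- qr.coef(qx, Y)                       # (1 + k) x TPs
  out <- list()
  for (i in seq_along(model$qtl_idx)) {
    if (!sequential) {
      Xd <- cbind(1, Xq[, -i, drop = FALSE])
      rss_drop <- colSums(qr.resid(qr(Xd), Y)^2)
    } else {
      # sequential: SS of adding QTL i after those earlier in map order
      Xbefore <- cbind(1, Xq[, seq_len(i - 1L), drop = FALSE])
      Xwith <- cbind(Xbefore, Xq[, i])
      rss_drop <- colSums(qr.resid(qr(Xbefore), Y)^2)
      rss_full_i <- colSums(qr.resid(qr(Xwith), Y)^2)
      rss_full <- rss_full_i
    }
    pve <- 100 * pmax(rss_drop - rss_full, 0) / pmax(tss, 1e-300)
    out[[i]] <- data.frame(
      qtl = i, chromosome = model$qtls$chromosome[i],
      position = model$qtls$position[i], tp = colnames(Y),
      effect = beta[i + 1L, ] / 2, pve = pve, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sequential") <- sequential
  res
}
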