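#' Cross-validated genomic predictive ability
#'
#' For each replicate, lines are split into a training fraction (default
#' 75%) and a validation set; a GBLUP model is fitted to the training
#' phenotypes and predictive ability `r` is the Pearson correlation
#' between the validation lines' adjusted values and their GEBVs.  With
#' `qtl_covariates = TRUE`, a single HKLOD scan with its own permutation
#' threshold is run inside each training set and the genotype
#' probabilities at significant peaks enter the model as fixed-effect
#' covariates.
#'
#' @param phenos Lines x traits matrix (each column cross-validated
#'   separately on the same splits).
#' @param K A `kinship` covering all lines.
#' @param n_reps Number of random splits (default 50).
#' @param train_frac Training fraction (default 0.75).
#' @param qtl_covariates Include training-set QTL peaks as fixed
#'   covariates?
#' @param gp,pc_scores Needed when `qtl_covariates = TRUE`: the
#'   `geno_probs` and the functional PC score matrix used for the HKLOD
#'   scan.
#' @param n_perm Permutations for the in-training threshold (default 200).
#' @param alpha Scan level (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `"cv_result"`: `replicates` (long data frame
#'   with `trait`, `rep`, `r`), `summary` (per-trait mean, se, mean
#'   Fisher-z, mean `h2g`).
#' @export
cross_validate <- function(phenos, K, n_reps = 50L, train_frac = 0.75,
                           qtl_covariates = FALSE, gp = NULL,
                           pc_scores = NULL, n_perm = 200L, alpha = 0.05,
                           seed = 1L) {
  stopifnot(n_reps >= 2L)
  phenos <- as.matrix(phenos)
  G <- if (inherits(K, "kinship")) K$G else as.matrix(K)
  n <- nrow(phenos)
  stopifnot(nrow(G) == n)
  if (qtl_covariates && (is.null(gp) || is.null(pc_scores)))
    stop("qtl_covariates = TRUE needs gp and pc_scores")
  traits <- colnames(phenos)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(phenos)))

  set.seed(seed)
  splits <- lapply(seq_len(n_reps), function(i)
    sort(sample.int(n, round(train_frac * n))))

  recs <- list(); h2gs <- matrix(NA_real_, n_reps, ncol(phenos))
  for (rep_i in seq_len(n_reps)) {
    train <- splits[[rep_i]]
    test <- setdiff(seq_len(n), train)
    qtl_idx <- integer()
    if (qtl_covariates) {
      gp_tr <- list(positions = gp$positions,
                    probs = gp$probs[train, , drop = FALSE])
      class(gp_tr) <- "geno_probs"
      pcs_tr <- pc_scores[train, , drop = FALSE]
      thr <- permutation_threshold(function(Yp)
        max(hklod_curve(Yp, gp_tr$probs)), pcs_tr, n_perm = n_perm,
        alpha = alpha, seed = seed + rep_i)
      sc <- scan_functional(pcs_tr, gp_tr, "HKLOD")
      pk <- find_peaks(sc, thr)
      if (nrow(pk))
        qtl_idx <- match(
          paste(pk$chromosome, pk$position),
          paste(gp$positions$chromosome, gp$positions$position))
    }
    for (j in seq_len(ncol(phenos))) {
      y_tr <- phenos[train, j]
      covs <- if (length(qtl_idx))
        gp$probs[train, qtl_idx, drop = FALSE] else NULL
      fit <- fit_gblup(y_tr, G, fixed_covariates = covs, train = train)
      pred <- fit$gebv[test]
      if (length(qtl_idx)) {
        # add the fixed QTL part to the prediction for held-out lines
        bq <- fit$beta[-1L]
        pred <- pred + drop(gp$probs[test, qtl_idx, drop = FALSE] %*% bq)
      }
      r <- if (stats::sd(pred) < 1e-12 || stats::sd(phenos[test, j]) < 1e-12)
        structure(0, constant = TRUE)
      else stats::cor(phenos[test, j], pred)
      recs[[length(recs) + 1L]] <- data.frame(
        trait = traits[j], rep = rep_i, r = as.numeric(r),
        n_qtl_covariates = length(qtl_idx), stringsAsFactors = FALSE)
      h2gs[rep_i, j] <- fit$h2g
    }
  }
  replicates <- do.call(rbind, recs)
  summary <- do.call(rbind, lapply(seq_along(traits), function(j) {
    rr <- replicates$r[replicates$trait == traits[j]]
    data.frame(trait = traits[j], mean_r = mean(rr),
               se_r = stats::sd(rr) / sqrt(n_reps),
               mean_z = mean(fisher_z(rr)),
               mean_h2g = mean(h2gs[, j]),
               se_h2g = stats::sd(h2gs[, j]) / sqrt(n_reps),
               stringsAsFactors = FALSE)
  }))
  structure(list(replicates = replicates, summary = summary,
                 n_reps = n_reps, train_frac = train_frac),
            class = "cv_result")
}

#' Scott-Knott clustering of scenario means
#'
#' Recursive binary partitioning of the ordered scenario means: at each
#' node the contiguous split maximising the between-group sum of squares
#' `B0` is tested with `lambda = pi/(2(pi-2)) B0 / sigma0^2` against a
#' chi-squared distribution with `k/(pi-2)` degrees of freedom (Scott &
#' Knott 1974 conventions).  Scenarios in the same terminal node share a
#' letter; letters are ordered `a, b, c, ...` by descending mean.
#' Typically applied to Fisher-z transformed predictive abilities.
#'
#' @param group_values Named list: scenario -> numeric replicate values.
#' @param alpha Test level (default 0.05).
#' @return Named character vector of group letters, one per scenario.
#' @export
scott_knott <- function(group_values, alpha = 0.05) {
  k_all <- length(group_values)
  if (k_all < 1L) stop("need at least one scenario")
  means <- vapply(group_values, mean, 0)
  ns <- lengths(group_values)
  # pooled within-scenario variance of a scenario mean
  dfs <- sum(ns - 1L)
  mse <- if (dfs > 0)
    sum(vapply(group_values, function(x) sum((x - mean(x))^2), 0)) / dfs
  else 0
  s2_mean <- mse / max(mean(ns), 1)
  v0 <- dfs

  groups <- rep(NA_integer_, k_all)
  counter <- 0L
  recurse <- function(idx) {
    k <- length(idx)
    if (k == 1L) {
      counter <<- counter + 1L
      groups[idx] <<- counter
      return(invisible())
    }
    ord <- idx[order(means[idx], decreasing = TRUE)]
    m <- means[ord]
    # best contiguous split by between-group SS
    b0 <- -Inf; cut <- 1L
    for (j in seq_len(k - 1L)) {
      g1 <- m[seq_len(j)]; g2 <- m[(j + 1L):k]
      b <- j * (mean(g1) - mean(m))^2 + (k - j) * (mean(g2) - mean(m))^2
      if (b > b0) { b0 <- b; cut <- j }
    }
    # Scott-Knott ML variance estimate at the node
    s0 <- (sum((m - mean(m))^2) + v0 * s2_mean) / (k + v0)
    lambda <- pi / (2 * (pi - 2)) * b0 / max(s0, 1e-300)
    df <- k / (pi - 2)
    crit <- stats::qchisq(1 - alpha, df)
    if (lambda > crit) {
      recurse(ord[seq_len(cut)])
      recurse(ord[(cut + 1L):k])
    } else {
      counter <<- counter + 1L
      groups[ord] <<- counter
    }
  }
  recurse(seq_len(k_all))
  letters_out <- letters[groups]
  stats::setNames(letters_out, names(group_values))
}
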