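#' Genotype probabilities on a pseudomarker grid
#'
#' Conditional probabilities of the second-parent homozygote at every marker
#' and pseudomarker position, given the observed flanking markers, from a
#' two-state Markov chain along each chromosome with RIL-expanded Haldane
#' transition probabilities (`ril_expansion(haldane_r(d))`).  Missing marker
#' calls are handled by the forward-backward algorithm.
#'
#' @param geno Lines x markers matrix in `{0,1,NA}`.
#' @param map `genetic_map` matching the columns of `geno`.
#' @param step Pseudomarker spacing in cM (default 1); the grid is the
#'   union of marker positions and an equispaced grid at `step`.
#' @return Object of class `"geno_probs"`: `positions` (data frame with
#'   `chromosome`, `position`, `marker`) and `probs` (lines x positions
#'   matrix of P(genotype class 1)).
#' @export
genotype_probs <- function(geno, map, step = 1) {
  stopifnot(step > 0)
  n_lines <- nrow(geno)
  pos_list <- list(); prob_list <- list()
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    mpos <- sub$position
    grid <- sort(unique(c(mpos, seq(min(mpos), max(mpos), by = step))))
    m_idx <- match(round(grid, 9), round(mpos, 9))     # marker at grid point?
    npos <- length(grid)

    # emission weights per line and state
    e0 <- matrix(1, n_lines, npos); e1 <- matrix(1, n_lines, npos)
    typed <- which(!is.na(m_idx))
    for (k in typed) {
      obs <- geno[, sub$marker[m_idx[k]]]
      e0[, k] <- ifelse(is.na(obs), 1, as.numeric(obs == 0))
      e1[, k] <- ifelse(is.na(obs), 1, as.numeric(obs == 1))
    }
    Rsw <- if (npos > 1L) ril_expansion(haldane_r(diff(grid))) else numeric()

    # forward
    f0 <- matrix(0, n_lines, npos); f1 <- matrix(0, n_lines, npos)
    f0[, 1L] <- 0.5 * e0[, 1L]; f1[, 1L] <- 0.5 * e1[, 1L]
    sc <- f0[, 1L] + f1[, 1L]
    f0[, 1L] <- f0[, 1L] / sc; f1[, 1L] <- f1[, 1L] / sc
    for (k in seq_len(npos - 1L)) {
      r <- Rsw[k]
      a0 <- (f0[, k] * (1 - r) + f1[, k] * r) * e0[, k + 1L]
      a1 <- (f0[, k] * r + f1[, k] * (1 - r)) * e1[, k + 1L]
      sc <- a0 + a1
      f0[, k + 1L] <- a0 / sc; f1[, k + 1L] <- a1 / sc
    }
    # backward
    b0 <- matrix(1, n_lines, npos); b1 <- matrix(1, n_lines, npos)
    for (k in rev(seq_len(npos - 1L))) {
      r <- Rsw[k]
      c0 <- b0[, k + 1L] * e0[, k + 1L]; c1 <- b1[, k + 1L] * e1[, k + 1L]
      b0[, k] <- c0 * (1 - r) + c1 * r
      b1[, k] <- c0 * r + c1 * (1 - r)
      sc <- b0[, k] + b1[, k]
      b0[, k] <- b0[, k] / sc; b1[, k] <- b1[, k] / sc
    }
    p1 <- (f1 * b1) / (f0 * b0 + f1 * b1)
    pos_list[[chr]] <- data.frame(
      chromosome = chr, position = grid,
      marker = ifelse(is.na(m_idx), NA_character_, sub$marker[m_idx]),
      stringsAsFactors = FALSE)
    prob_list[[chr]] <- p1
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  probs <- do.call(cbind, prob_list)
  rownames(probs) <- rownames(geno)
  structure(list(positions = positions, probs = probs),
            class = "geno_probs")
}
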