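# Shared fixtures, built in code at load time.  Sizes are kept small so the
# default test run stays fast; the heavier calibration checks live in
# test-acceptance.R.

# compact linkage map + RIL genotypes + genotype probabilities
fx_map <- simulate_map(n_chrom = 5L, markers_per_chrom = 50L,
                       length_cM = 100, seed = 101L)
fx_geno <- simulate_ril_genotypes(fx_map, n_lines = 197L, seed = 102L)
fx_gp <- genotype_probs(fx_geno, fx_map, step = 1)

# null per-TP adjusted values with the season-long FA(1) signature:
# loadings (hence genetic variance) growing over the season
make_null_blups <- function(n_lines = 197L, tps = default_tps(),
                            seed = 1L, line_ids = rownames(fx_geno)) {
  set.seed(seed)
  nt <- length(tps)
  lam <- seq(0.02, 0.10, length.out = nt)
  psi <- (0.3 * lam)^2
  Y <- outer(stats::rnorm(n_lines), lam) +
    matrix(stats::rnorm(n_lines * nt), n_lines, nt) %*% diag(sqrt(psi))
  dimnames(Y) <- list(line_ids[seq_len(n_lines)], tps)
  Y
}

# PC scores + linear TP->score projection for a fixed basis size (no CV),
# shared by the scan and power tests
fx_scores_of <- function(Y, tps = default_tps(), n_basis = 7L) {
  sp <- fit_splines(Y, tps, candidate_bases = n_basis, seed = 1L)
  pcs <- functional_pca(sp)
  list(sp = sp, pcs = pcs, projection = score_projection(sp, pcs))
}

# small augmented-field phenotype for spatial-model tests
make_small_trial <- function(seed = 1L, n_lines = 100L, field = c(10L, 12L),
                             tps = c(100L, 150L), h2 = 0.6,
                             phi_c = 0.4, phi_r = 0.4, sigma2_xi_frac = 0.5) {
  grid <- tp_grid(tps)
  map <- simulate_map(2L, 10L, 100, seed = seed)
  geno <- simulate_ril_genotypes(map, n_lines, seed = seed + 1L)
  s2g <- 0.01
  s2e <- s2g * (1 - h2) / h2
  truth <- trial_truth(grid$tps, lambda = sqrt(0.9 * s2g),
                       psi = 0.1 * s2g,
                       sigma2_xi = sigma2_xi_frac * s2e, phi_c = phi_c,
                       phi_r = phi_r,
                       sigma2_eta = (1 - sigma2_xi_frac) * s2e)
  sim <- simulate_trial(geno, map, grid, truth, field = field,
                        n_check_plots = 20L, seed = seed + 2L)
  c(list(geno = geno, map = map, grid = grid), sim)
}
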