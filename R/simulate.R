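#' Haldane map function
#'
#' Converts a map distance in centiMorgans to a recombination fraction under
#' no interference: r = 0.5 (1 - exp(-2d/100)).
#'
#' @param d Map distance in centiMorgans (vectorised, non-negative).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Map expansion for selfed recombinant inbred lines
#'
#' Probability that two loci at meiotic recombination fraction `r` carry
#' different parental alleles in a fully inbred selfed RIL: R = 2r/(1+2r).
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @return RIL-level switch probability.
#' @export
ril_expansion <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("recombination fraction must be in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Simulate a genetic map
#'
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param length_cM Chromosome length in cM.
#' @param seed Integer seed.
#' @param random_positions If `TRUE`, positions are uniform random in
#'   `[0, length_cM]` (first marker forced to 0); otherwise evenly spaced
#'   from 0 to `length_cM`.
#' @return A `genetic_map`.
#' @export
simulate_map <- function(n_chrom, markers_per_chrom, length_cM, seed = 1L,
                         random_positions = FALSE) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 2, length_cM > 0)
  set.seed(seed)
  maps <- lapply(seq_len(n_chrom), function(chr) {
    pos <- if (random_positions) {
      p <- sort(stats::runif(markers_per_chrom, 0, length_cM))
      p - p[1L]
    } else {
      seq(0, length_cM, length.out = markers_per_chrom)
    }
    data.frame(chromosome = sprintf("C%d", chr),
               marker = sprintf("C%d_M%03d", chr, seq_len(markers_per_chrom)),
               position = pos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, maps)
  genetic_map(df$chromosome, df$marker, df$position)
}

#' Simulate fully homozygous RIL genotypes along a map
#'
#' Each line is an independent two-state Markov chain along each chromosome:
#' the first marker allele is Bernoulli(0.5) and adjacent markers switch
#' parental origin with probability `ril_expansion(haldane_r(d))`.
#' Chromosomes are independent; lines are fully homozygous.
#'
#' @param map A `genetic_map`.
#' @param n_lines Number of RILs (>= 2).
#' @param seed Integer seed.
#' @return Lines x markers integer matrix in `{0,1}` with line ids
#'   `L001, ...` and marker ids from the map.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = 1L) {
  stopifnot(n_lines >= 2)
  set.seed(seed)
  chrs <- unique(map$chromosome)
  blocks <- lapply(chrs, function(chr) {
    pos <- map$position[map$chromosome == chr]
    m <- length(pos)
    g <- matrix(0L, n_lines, m)
    g[, 1L] <- stats::rbinom(n_lines, 1L, 0.5)
    if (m > 1L) {
      Rsw <- ril_expansion(haldane_r(diff(pos)))
      for (j in 2:m) {
        sw <- stats::rbinom(n_lines, 1L, Rsw[j - 1L])
        g[, j] <- ifelse(sw == 1L, 1L - g[, j - 1L], g[, j - 1L])
      }
    }
    g
  })
  geno <- do.call(cbind, blocks)
  dimnames(geno) <- list(sprintf("L%03d", seq_len(n_lines)), map$marker)
  geno
}

#' Time-point grid with phenological stages
#'
#' Defines the sampling days (days after sowing, DAS) and assigns each to a
#' growth stage: tillering (up to `tillering_end`), stem elongation (up to
#' `stem_end`) and heading/flowering afterwards.  Defaults reproduce a
#' winter-wheat season scanned from DAS 23 to 228 with stage boundaries at
#' DAS 128/155 and 209/214.
#'
#' @param tps Strictly increasing integer DAS values.
#' @param tillering_end Last DAS counted as tillering.
#' @param stem_end Last DAS counted as stem elongation.
#' @return A list of class `"tp_grid"` with `tps` and `stages` (factor).
#' @export
tp_grid <- function(tps = default_tps(), tillering_end = 128L,
                    stem_end = 209L) {
  tps <- as.integer(tps)
  if (any(diff(tps) <= 0)) stop("time points must be strictly increasing")
  stages <- cut(tps, c(-Inf, tillering_end, stem_end, Inf),
                labels = c("tillering", "stem_elongation", "heading_flowering"))
  structure(list(tps = tps, stages = stats::setNames(stages, tps)),
            class = "tp_grid")
}

#' Default 26-time-point sampling grid (DAS 23-228)
#'
#' Fourteen tillering, eight stem-elongation and four heading/flowering
#' sampling days, matching a season-long scan of a winter wheat trial.
#' @return Integer vector of 26 DAS values.
#' @export
default_tps <- function() {
  c(23L, 30L, 37L, 44L, 51L, 57L, 64L, 70L, 78L, 84L, 91L, 98L, 119L, 128L,
    155L, 166L, 172L, 181L, 187L, 193L, 201L, 209L,
    214L, 219L, 223L, 228L)
}

#' Ground-truth specification for a synthetic trial
#'
#' Bundles the genetic architecture used by [simulate_trial()]: QTLs with
#' per-time-point allele-substitution effects, rank-1 factor-analytic
#' loadings and specific variances of the polygenic effect, spatial AR1xAR1
#' error and per-time-point nugget variances.
#'
#' @param tps Integer DAS vector the per-TP vectors refer to.
#' @param qtls List of QTLs, each a list with `chromosome`, `position` (cM)
#'   and `effect` (per-TP allele-substitution effect, length = #TPs).
#' @param lambda Per-TP factor loadings (genetic SD scale).
#' @param psi Per-TP specific genetic variances (>= 0).
#' @param sigma2_xi Spatial variance; scalar or per-TP vector.
#' @param phi_c,phi_r AR1 autocorrelations along columns and rows (|.| < 1).
#' @param sigma2_eta Per-TP nugget variances (scalar recycled).
#' @param mu Per-TP population mean curve; default from
#'   [growth_mean_curve()].
#' @param check_effects Named per-check fixed offsets (m), constant over TPs.
#' @return A list of class `"trial_truth"`.
#' @export
trial_truth <- function(tps, qtls = list(), lambda = rep(0, length(tps)),
                        psi = rep(0, length(tps)), sigma2_xi = 0,
                        phi_c = 0, phi_r = 0, sigma2_eta = 0,
                        mu = growth_mean_curve(tps),
                        check_effects = numeric()) {
  nt <- length(tps)
  lambda <- rep_len(lambda, nt)
  psi <- rep_len(psi, nt)
  sigma2_xi <- rep_len(sigma2_xi, nt)
  sigma2_eta <- rep_len(sigma2_eta, nt)
  mu <- rep_len(mu, nt)
  stopifnot(all(psi >= 0), all(sigma2_xi >= 0), all(sigma2_eta >= 0),
            abs(phi_c) < 1, abs(phi_r) < 1)
  for (q in qtls)
    if (length(q$effect) != nt)
      stop("each QTL effect profile needs one value per time point")
  structure(list(tps = as.integer(tps), qtls = qtls, lambda = lambda,
                 psi = psi, sigma2_xi = sigma2_xi, phi_c = phi_c,
                 phi_r = phi_r, sigma2_eta = sigma2_eta, mu = mu,
                 check_effects = check_effects),
            class = "trial_truth")
}

#' Accelerating-then-linear mean growth curve
#'
#' Logistic growth up to a changepoint (default DAS 141, the
#' tillering/stem-elongation boundary), continued linearly at the tangent
#' slope afterwards.  Defaults give ~0.06 m at DAS 23 and ~1.0 m at DAS 228,
#' a typical tall-wheat season.
#'
#' @param tps DAS values to evaluate at.
#' @param base Lower asymptote (m).
#' @param amplitude Logistic amplitude (m).
#' @param midpoint Logistic midpoint (DAS).
#' @param scale Logistic time scale (days).
#' @param changepoint DAS where growth switches to linear.
#' @return Numeric vector of mean heights (m).
#' @export
growth_mean_curve <- function(tps, base = 0.05, amplitude = 0.69,
                              midpoint = 141, scale = 25, changepoint = 141) {
  logis <- function(t) base + amplitude / (1 + exp(-(t - midpoint) / scale))
  slope <- amplitude / scale * {
    e <- exp(-(changepoint - midpoint) / scale); e / (1 + e)^2
  }
  ifelse(tps <= changepoint, logis(tps),
         logis(changepoint) + slope * (tps - changepoint))
}

#' QTL temporal effect-profile presets
#'
#' Builds a per-time-point allele-substitution effect vector of the three
#' archetypes seen in longitudinal mapping: `persistent` (constant over the
#' season), `transient` (a single time point) and `stage` (a contiguous
#' phenological stage).
#'
#' @param grid A `tp_grid`.
#' @param type One of `"persistent"`, `"transient"`, `"stage"`.
#' @param alpha Effect size (trait units) on the nonzero part.
#' @param at For `transient`, the DAS of the expressed time point; for
#'   `stage`, the stage name.
#' @return Numeric effect vector, one entry per time point.
#' @export
qtl_profile <- function(grid, type = c("persistent", "transient", "stage"),
                        alpha, at = NULL) {
  type <- match.arg(type)
  nt <- length(grid$tps)
  eff <- rep(0, nt)
  if (type == "persistent") eff[] <- alpha
  else if (type == "transient") {
    if (is.null(at)) at <- grid$tps[ceiling(nt / 2)]
    eff[match(as.integer(at), grid$tps)] <- alpha
  } else {
    if (is.null(at)) at <- "stem_elongation"
    eff[grid$stages == at] <- alpha
  }
  eff
}

#' Simulate a longitudinal augmented field trial
#'
#' Generates plot-level phenotypes
#' `value = mu_t + check_t + g_line,t + xi + eta` where the polygenic
#' deviation has the rank-1 factor-analytic covariance `lambda lambda' + Psi`
#' across time points plus the QTL terms `x_line * alpha_q,t` (genotype coded
#' -1/+1 so `alpha` is the allele-substitution effect and the two homozygote
#' class means differ by `2 alpha`), `xi` is an AR1xAR1 spatial field drawn
#' independently per time point, and `eta` is an independent nugget.
#' Check genotypes are replicated fixed-effect entries; RILs occupy one plot
#' each (augmented design).
#'
#' @param geno RIL genotype matrix (`{0,1}`), lines x markers.
#' @param map `genetic_map` matching `geno`.
#' @param grid A `tp_grid`.
#' @param truth A `trial_truth` (its `tps` must equal `grid$tps`).
#' @param field `c(n_rows, n_cols)`; must hold all plots.
#' @param n_check_plots Number of check plots, spread evenly through the
#'   field and cycled over the check genotypes.
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `pheno` (a `pheno_long`), `truth` and `g` (the realised
#'   lines x TPs total genetic deviations, for recovery checks).
#' @export
simulate_trial <- function(geno, map, grid, truth, field = c(16L, 15L),
                           n_check_plots = 40L, seed = 1L) {
  stopifnot(identical(truth$tps, grid$tps))
  set.seed(seed)
  n_lines <- nrow(geno)
  nt <- length(grid$tps)
  n_checks <- length(truth$check_effects)
  if (n_checks == 0L && n_check_plots > 0L) {
    truth$check_effects <- stats::setNames(
      seq(-0.02, 0.02, length.out = 5L), sprintf("CHK%d", 1:5))
    n_checks <- 5L
  }
  n_plots <- n_lines + n_check_plots
  if (prod(field) < n_plots) stop("field too small for all plots")

  # plot layout: fill row-major; check plots at evenly spaced positions
  idx <- seq_len(n_plots)
  plot_row <- ((idx - 1L) %/% field[2L]) + 1L
  plot_col <- ((idx - 1L) %% field[2L]) + 1L
  check_pos <- if (n_check_plots > 0L)
    unique(round(seq(1L, n_plots, length.out = n_check_plots))) else integer()
  is_check <- idx %in% check_pos
  entries <- character(n_plots)
  entries[!is_check] <- sample(rownames(geno))
  if (any(is_check))
    entries[is_check] <- rep_len(names(truth$check_effects), sum(is_check))

  # polygenic deviations: rank-1 FA plus QTL effects on +/-1 coded genotypes.
  # The common factor is a genome-wide polygenic score (every marker gets a
  # small effect), standardised to unit variance, so the factor part of the
  # genetic variance is marker-heritable -- as it is in a real RIL panel.
  W <- scale(geno, scale = FALSE)
  f_raw <- drop(W %*% stats::rnorm(ncol(geno)))
  f <- if (stats::sd(f_raw) > 0) drop(scale(f_raw)) else stats::rnorm(n_lines)
  g_mat <- outer(f, truth$lambda) +
    matrix(stats::rnorm(n_lines * nt), n_lines, nt) %*% diag(sqrt(truth$psi), nt)
  for (q in truth$qtls) {
    xm <- nearest_marker(map, q$chromosome, q$position)
    x <- 2 * geno[, xm] - 1            # -1/+1 coding
    g_mat <- g_mat + outer(x, q$effect)
  }
  dimnames(g_mat) <- list(rownames(geno), grid$tps)

  # spatial AR1xAR1 field per TP + nugget
  Lc <- ar1_chol(field[2L], truth$phi_c)
  Lr <- ar1_chol(field[1L], truth$phi_r)
  recs <- vector("list", nt)
  for (t in seq_len(nt)) {
    xi_field <- Lr %*% matrix(stats::rnorm(prod(field)), field[1L], field[2L]) %*% t(Lc)
    xi <- sqrt(truth$sigma2_xi[t]) * xi_field[cbind(plot_row, plot_col)]
    eta <- stats::rnorm(n_plots, 0, sqrt(truth$sigma2_eta[t]))
    gval <- numeric(n_plots)
    if (any(is_check)) gval[is_check] <- truth$check_effects[entries[is_check]]
    gval[!is_check] <- g_mat[entries[!is_check], t]
    recs[[t]] <- data.frame(line = entries, is_check = is_check,
                            row = plot_row, column = plot_col,
                            tp = grid$tps[t],
                            value = truth$mu[t] + gval + xi + eta,
                            stringsAsFactors = FALSE)
  }
  pheno <- pheno_long(do.call(rbind, recs))
  list(pheno = pheno, truth = truth, g = g_mat)
}

# lower Cholesky factor of an AR1 correlation matrix
#' @keywords internal
ar1_chol <- function(n, phi) {
  if (n == 1L) return(matrix(1, 1, 1))
  t(chol(phi^abs(outer(seq_len(n), seq_len(n), "-"))))
}

#' @keywords internal
nearest_marker <- function(map, chromosome, position) {
  sub <- map[map$chromosome == chromosome, , drop = FALSE]
  if (!nrow(sub)) stop("no markers on chromosome ", chromosome)
  sub$marker[which.min(abs(sub$position - position))]
}

#' Season-calibrated synthetic trial preset
#'
#' One call that emulates the study conditions the package is validated
#' against: 197 RILs scanned at 26 time points (DAS 23-228) on a 21
#' chromosome map, genetic variance growing with the mean curve under an
#' FA(1) structure, AR1xAR1 spatial error, per-time-point heritability
#' calibrated to 0.68 at plot level, and four QTLs with persistent, early
#' stage-specific and late stage-specific temporal profiles.
#'
#' @param seed Integer seed.
#' @param n_lines Number of RILs.
#' @param n_chrom,markers_per_chrom,length_cM Map dimensions (defaults give
#'   21 x 111 = 2331 markers, ~110 cM chromosomes).
#' @param h2_plot Target per-time-point plot-level broad-sense heritability.
#' @param with_qtls Include the four preset QTLs?
#' @return List with `geno`, `map`, `grid`, `truth`, `pheno`, `g`.
#' @export
preset_trial <- function(seed = 1L, n_lines = 197L, n_chrom = 21L,
                         markers_per_chrom = 111L, length_cM = 110,
                         h2_plot = 0.68, with_qtls = TRUE) {
  grid <- tp_grid()
  map <- simulate_map(n_chrom, markers_per_chrom, length_cM, seed = seed)
  geno <- simulate_ril_genotypes(map, n_lines, seed = seed + 1L)

  mu <- growth_mean_curve(grid$tps)
  # genetic SD grows with the season: ~2 cm early to ~10 cm at maturity
  sd_g <- 0.02 + 0.08 * (mu - min(mu)) / (max(mu) - min(mu))
  sigma2_g <- sd_g^2

  qtls <- list()
  if (with_qtls) {
    a <- sd_g * 0.45                       # per-TP scale for QTL effects
    # target chromosomes, folded into range for reduced-size maps
    qc <- sprintf("C%d", pmin(c(2L, 5L, 8L, 7L), n_chrom))
    qtls <- list(
      list(chromosome = qc[1L], position = 55,
           effect = qtl_profile(grid, "persistent", 1) * a),      # persistent
      list(chromosome = qc[2L], position = 30,
           effect = qtl_profile(grid, "stage", 1, "tillering") * a),
      list(chromosome = qc[3L], position = 70,
           effect = qtl_profile(grid, "stage", 1, "tillering") * a * 0.8),
      list(chromosome = qc[4L], position = 40,
           effect = qtl_profile(grid, "stage", 1, "heading_flowering") * a))
  }
  var_qtl <- Reduce(`+`, lapply(qtls, function(q) q$effect^2), rep(0, length(mu)))
  var_fa <- pmax(sigma2_g - var_qtl, 0.05 * sigma2_g)
  lambda <- sqrt(0.9 * var_fa)
  psi <- 0.1 * var_fa
  # error split keeps plot-level H2 at h2_plot for every TP
  err_ratio <- (1 - h2_plot) / h2_plot
  sigma2_eps <- sigma2_g * err_ratio
  truth <- trial_truth(grid$tps, qtls = qtls, lambda = lambda, psi = psi,
                       sigma2_xi = 0.55 * sigma2_eps, phi_c = 0.4,
                       phi_r = 0.4, sigma2_eta = 0.45 * sigma2_eps, mu = mu)
  sim <- simulate_trial(geno, map, grid, truth, field = c(16L, 15L),
                        n_check_plots = 40L, seed = seed + 2L)
  c(list(geno = geno, map = map, grid = grid), sim)
}

#' Write a trial truth object to YAML
#' @param truth A `trial_truth`.
#' @param path Output path.
#' @export
write_trial_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}
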