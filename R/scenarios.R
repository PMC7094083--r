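#' Built-in time-point selection scenarios
#'
#' The nine selection scenarios compared in the package's analyses:
#' systematic (SY) spreads of five or ten sampling days across the season,
#' growth-stage-informed (GS) selections weighted toward late phenology,
#' and the full 26-day grid.  Stage counts refer to tillering, stem
#' elongation and heading/flowering.
#'
#' @return Named list of `tp_scenario` objects `R1` ... `R9`, each with
#'   `name`, `approach` (`"SY"`, `"GS"` or `"full"`), `das_list` and
#'   `stage_counts`.
#' @export
builtin_scenarios <- function() {
  def <- list(
    R1 = list("SY", c(23, 70, 128, 181, 228), c(3, 1, 1)),
    R2 = list("SY", c(23, 78, 155, 193, 228), c(2, 2, 1)),
    R3 = list("GS", c(70, 172, 219, 223, 228), c(1, 1, 3)),
    R4 = list("GS", c(181, 214, 219, 223, 228), c(0, 1, 4)),
    R5 = list("SY", c(23, 44, 64, 84, 119, 155, 172, 187, 214, 228),
              c(5, 3, 2)),
    R6 = list("SY", c(37, 57, 70, 98, 119, 155, 172, 193, 219, 228),
              c(5, 3, 2)),
    R7 = list("GS", c(84, 155, 166, 181, 193, 209, 214, 219, 223, 228),
              c(1, 5, 4)),
    R8 = list("GS", c(166, 172, 181, 187, 193, 209, 214, 219, 223, 228),
              c(0, 6, 4)),
    R9 = list("full", default_tps(), c(14, 8, 4)))
  lapply(stats::setNames(names(def), names(def)), function(nm) {
    d <- def[[nm]]
    structure(list(name = nm, approach = d[[1L]],
                   das_list = as.integer(d[[2L]]),
                   stage_counts = stats::setNames(
                     as.integer(d[[3L]]),
                     c("tillering", "stem_elongation", "heading_flowering"))),
              class = "tp_scenario")
  })
}

#' Subset phenotypes to a time-point scenario
#'
#' @param scenario A `tp_scenario` (or name of a built-in one).
#' @param pheno A `pheno_long`.
#' @return The row subset of `pheno` at the scenario's DAS values.
#' @export
select_tps <- function(scenario, pheno) {
  if (is.character(scenario)) scenario <- builtin_scenarios()[[scenario]]
  absent <- setdiff(scenario$das_list, unique(pheno$tp))
  if (length(absent))
    stop("scenario DAS not present in the data: ",
         paste(absent, collapse = ", "))
  out <- pheno[pheno$tp %in% scenario$das_list, , drop = FALSE]
  class(out) <- class(pheno)
  out
}

# deterministic stage sub-seed from the master seed and stage name
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147480000L
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Orchestrates simulate -> stage-one BLUPs -> smoothing/fPCA -> QTL scans
#' -> (optionally) power simulation and genomic prediction, writing
#' versioned delimited-text outputs plus a YAML summary and a structured
#' log into `out_dir`.  Every stochastic stage receives a sub-seed derived
#' from the master seed and the stage name, so stages are individually
#' reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param scenario Scenario name (see [builtin_scenarios()]) or `"R9"`
#'   for the full grid.
#' @param sim Optional pre-generated trial (the result of
#'   [preset_trial()]); by default one is generated with the preset.
#' @param n_perm Permutations for scan thresholds.
#' @param run_scans,run_power_stage,run_prediction Toggles for the
#'   heavier stages.
#' @param power_pve,power_n_iter Power-stage settings.
#' @param n_cv_reps Cross-validation replicates.
#' @return Invisibly, a list with the main per-stage results; the same
#'   content is written under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, scenario = "R9", sim = NULL,
                         n_perm = 200L, run_scans = TRUE,
                         run_power_stage = FALSE, run_prediction = TRUE,
                         power_pve = 0.2, power_n_iter = 100L,
                         n_cv_reps = 50L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(stage, msg)
    cat(sprintf("%s\t%s\t%s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = logf, append = TRUE)

  if (is.null(sim)) {
    log_line("simulate", paste("seed", stage_seed(seed, "simulate")))
    sim <- preset_trial(seed = stage_seed(seed, "simulate"))
  }
  scen <- builtin_scenarios()[[scenario]]
  pheno <- select_tps(scen, sim$pheno)
  tps <- scen$das_list

  log_line("blups", paste(length(tps), "time points"))
  s1 <- stage_one_blups(pheno, tps = tps)
  write_result_table(data.frame(line = rownames(s1$blup), s1$blup,
                                check.names = FALSE),
                     file.path(out_dir, "blups.tsv"),
                     list(stage = "blups", scenario = scenario, seed = seed))
  write_result_table(s1$heritability, file.path(out_dir, "heritability.tsv"),
                     list(stage = "blups"))

  log_line("smooth", "B-spline + fPCA")
  sp <- fit_splines(s1$blup, tps, seed = stage_seed(seed, "smooth"))
  pcs <- functional_pca(sp)
  write_result_table(data.frame(line = rownames(sp$coef_matrix),
                                sp$coef_matrix, check.names = FALSE),
                     file.path(out_dir, "spline_coefs.tsv"),
                     list(n_basis = sp$n_basis))
  write_result_table(data.frame(pc = seq_along(pcs$varprop),
                                varprop = pcs$varprop),
                     file.path(out_dir, "pc_varprop.tsv"), list())

  out <- list(sim = sim, scenario = scen, stage_one = s1, splines = sp,
              pcs = pcs)

  if (run_scans) {
    log_line("scan", paste("n_perm", n_perm))
    gp <- genotype_probs(sim$geno, sim$map, step = 1)
    perms <- make_perms(nrow(s1$blup), n_perm,
                        stage_seed(seed, "scan"))
    scans <- list()
    for (s in c("HKLOD", "MLOD", "SLOD")) {
      Yin <- if (s == "HKLOD") pcs$scores else s1$blup
      sc <- scan_functional(Yin, gp, s)
      sc$threshold <- permutation_threshold(function(Yp)
        max(scan_functional(Yp, gp, s)$lod), Yin, perms = perms)
      sc$peaks <- find_peaks(sc, sc$threshold)
      scans[[s]] <- sc
      mod <- stepwise_multiple_qtl(Yin, gp, s, penalty = sc$threshold)
      scans[[s]]$model <- mod
    }
    peak_report <- do.call(rbind, lapply(names(scans), function(s) {
      pk <- scans[[s]]$peaks
      if (!nrow(pk)) return(NULL)
      cbind(statistic = s, pk)
    }))
    if (!is.null(peak_report))
      write_result_table(peak_report, file.path(out_dir, "peaks.tsv"),
                         list(n_perm = n_perm))
    out$gp <- gp
    out$scans <- scans
  }

  if (run_power_stage) {
    log_line("power", paste("pve", power_pve, "n_iter", power_n_iter))
    proj <- score_projection(sp, pcs)
    pw <- lapply(c("persistent", "transient"), function(ty)
      cbind(qtl_type = ty,
            run_power(s1$blup, sim$geno, out$gp, pcs$scores,
                      pve_grid = power_pve, qtl_type = ty,
                      n_iter = power_n_iter, n_perm = n_perm,
                      projection = proj,
                      seed = stage_seed(seed, paste0("power_", ty)))))
    out$power <- do.call(rbind, pw)
    write_result_table(out$power, file.path(out_dir, "power.tsv"),
                       list(n_iter = power_n_iter, n_perm = n_perm))
  }

  if (run_prediction) {
    log_line("predict", paste(n_cv_reps, "replicates"))
    K <- vanraden_g(sim$geno)
    nb <- sp$n_basis
    traits <- cbind(sp$coef_matrix[, c(nb - 1L, nb)], pcs$scores[, 1L])
    colnames(traits) <- c(paste0("bs", nb - 1L), paste0("bs", nb), "pc1")
    cv <- cross_validate(traits, K, n_reps = n_cv_reps,
                         seed = stage_seed(seed, "predict"))
    out$cv <- cv
    write_result_table(cv$summary, file.path(out_dir, "prediction.tsv"),
                       list(n_reps = n_cv_reps))
  }

  summary <- list(seed = seed, scenario = scenario,
                  n_tps = length(tps),
                  mean_H2 = mean(s1$heritability$H2),
                  n_basis = sp$n_basis,
                  pc12_varprop = sum(pcs$varprop[1:2]))
  if (run_scans)
    summary$detected_chromosomes <- lapply(out$scans, function(s)
      unique(s$peaks$chromosome))
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(out)
}
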