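#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end dynamic-docking
#' analysis with the standard protocol constants as defaults: K-means on
#' the PC dimensions covering >90% of the variance, R-value merge threshold
#' 0.7, CFE stable-set cutoff 2.5 kcal/mol, landscape display cutoff 5
#' kcal/mol, 2.5 Angstrom dissociation windows and analysis temperatures
#' 300/400 K.
#'
#' @param system a [toy_system()] (e.g. from [make_cryptic_toy()]).
#' @param mcmd an [mcmd_config()].
#' @param production_sweeps,n_parallel production run size.
#' @param production_save_every sweeps between saved production frames
#'   (coarser than the flattening runs; decorrelates the analyzed frames).
#' @param T_analysis canonical analysis temperature (K).
#' @param k_prime cluster count (`NULL`: [default_k_prime()] of the
#'   production size).
#' @param n_restarts k-means++ restarts.
#' @param variance_threshold cumulative PC variance threshold (percent).
#' @param merge_threshold R-value merge threshold.
#' @param cfe_cutoff stable-set CFE cutoff (kcal/mol).
#' @param fel_cutoff landscape display cutoff (kcal/mol).
#' @param window_width dissociation window width (Angstrom).
#' @param stability_temps probe temperatures for stability scoring.
#' @param do_refine run refinement/stability of the stable set?
#' @param do_pathway extract the dissociation pathway?
#' @param seed base seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(system, mcmd = mcmd_config(),
                            production_sweeps = 50000, n_parallel = 4,
                            production_save_every = 10,
                            T_analysis = 300, k_prime = NULL, n_restarts = 10,
                            variance_threshold = 90, merge_threshold = 0.7,
                            cfe_cutoff = 2.5, fel_cutoff = 5,
                            window_width = 2.5,
                            stability_temps = c(300, 400),
                            do_refine = TRUE, do_pathway = TRUE, seed = 1) {
  stopifnot(merge_threshold > 0, merge_threshold <= 1, cfe_cutoff > 0,
            fel_cutoff > 0, window_width > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full dynamic-docking analysis
#'
#' Orchestrates the stages on one system: multicanonical bias flattening,
#' production sampling, canonical reweighting, distance-feature PCA and
#' free-energy landscape, K-means clustering with cluster free energies,
#' representative picking and R-value merging, optional canonical
#' refinement and two-temperature stability scoring of the stable set, and
#' optional dissociation-pathway extraction from the top-ranked
#' representative. Identical config and seed give an identical report.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `report_bundle` with elements `bias`,
#'   `production`, `weights`, `projection`, `fel`, `clusters`, `cfe`,
#'   `representatives`, `rep_table`, `stability`, `refined`, `pathway`,
#'   `similarity`, `lambda`, `log` (per-stage diagnostics).
#' @export
run_docking_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sys <- config$system
  log <- list(seed = config$seed)

  flat <- iterate_bias(sys, config$mcmd, seed = config$seed)
  log$flatness <- flat$flatness
  log$bias_converged <- flat$converged

  prod <- run_mcmd(sys, flat$bias, config$production_sweeps,
                   seed = config$seed + 1000,
                   n_parallel = config$n_parallel,
                   save_every = config$production_save_every,
                   step = config$mcmd$step)
  w <- canonical_weights(prod, flat$bias, config$T_analysis)
  log$ess <- w$ess

  topo_struct <- toy_structure(sys)
  spec <- selection_spec(topo_struct,
                         receptor_anchors = select_atoms(topo_struct,
                                                         role = "receptor"),
                         ligand_atoms = select_atoms(topo_struct,
                                                     role = "ligand"),
                         exclusion = 3)
  feats <- build_distance_features(prod, spec)
  proj <- pca_fit_project(feats)
  dims <- n_components(proj, config$variance_threshold)
  fel <- compute_fel(proj, w, T = config$T_analysis,
                     cutoff = config$fel_cutoff)

  kp <- config$k_prime %||% default_k_prime(n_snapshots(prod))
  clus <- cluster_pc(proj, kp, dims = dims, seed = config$seed + 2000,
                     n_restarts = config$n_restarts)
  cfe <- cluster_free_energy(clus, w, T = config$T_analysis)
  reps <- pick_representatives(clus, proj)
  repset <- merge_by_rvalue(cfe, reps, prod,
                            threshold = config$merge_threshold,
                            cfe_cutoff = config$cfe_cutoff,
                            T = config$T_analysis)
  rep_table <- representative_table(repset, proj, fel)
  log$k_prime <- kp; log$dims <- dims
  log$n_representatives <- nrow(repset)
  log$n_stable <- sum(repset$stable)

  stability <- refined <- NULL
  if (config$do_refine) {
    stable_rows <- which(repset$stable)
    refined <- list(); stability <- list()
    for (r in stable_rows) {
      x0 <- matrix(prod$coords[repset$snapshot[r], ], ncol = 3, byrow = TRUE)
      refined[[as.character(r)]] <-
        refine_representative(x0, sys, seed = config$seed + 3000 + r)
      stability[[as.character(r)]] <-
        stability_score(x0, sys, temps = config$stability_temps,
                        seed = config$seed + 4000 + r)
    }
  }

  lambda <- lambda_series(prod)
  pathway <- similarity <- NULL
  if (config$do_pathway && nrow(repset) > 0) {
    start <- repset$snapshot[1]
    wpath <- make_windows(lambda[start] - config$window_width / 2,
                          max(lambda) + 1e-6, config$window_width)
    # truncate at the first empty window so the path stays connected
    occ <- vapply(seq_len(nrow(wpath)), function(k)
      any(lambda >= wpath$lo[k] & lambda < wpath$hi[k] + 1e-12), logical(1))
    last <- if (all(occ)) nrow(wpath) else which(!occ)[1] - 1
    if (last >= 2) {
      wpath <- wpath[seq_len(last), ]
      pathway <- extract_pathway(prod, lambda, start, wpath)
      similarity <- window_similarity(pathway)
    } else {
      log$pathway_note <- "fewer than two occupied windows; pathway skipped"
    }
  }

  structure(list(bias = flat$bias, production = prod, weights = w,
                 projection = proj, fel = fel, clusters = clus, cfe = cfe,
                 representatives = repset, rep_table = rep_table,
                 stability = stability, refined = refined,
                 pathway = pathway, similarity = similarity,
                 lambda = lambda, log = log, config = config),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Dynamic-docking analysis report\n")
  cat(sprintf("  bias: %d flattening iteration(s), converged: %s\n",
              length(x$log$flatness), x$log$bias_converged))
  cat(sprintf("  production: %d snapshots, ESS at %g K = %.1f\n",
              n_snapshots(x$production), x$weights$T, x$log$ess))
  cat(sprintf("  clustering: k' = %d on %d PC dim(s)\n",
              x$log$k_prime, x$log$dims))
  cat(sprintf("  representatives: %d retained, %d stable (CFE < %.1f kcal/mol)\n",
              x$log$n_representatives, x$log$n_stable,
              x$config$cfe_cutoff))
  if (!is.null(x$pathway)) {
    cat(sprintf("  pathway: %d windows, min neighbor R = %.3f\n",
                nrow(x$pathway), min(x$pathway$r_prev, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write the report tables to a directory
#'
#' Emits the representative table, stability table, landscape grid and
#' pathway similarity table as delimited text files.
#'
#' @param report a [run_docking_analysis()] result.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$rep_table, file.path(dir, "representatives.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_fel(report$fel, file.path(dir, "fel.tsv"))
  if (!is.null(report$similarity)) {
    utils::write.table(report$similarity, file.path(dir, "pathway.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$stability)) {
    st <- do.call(rbind, lapply(names(report$stability), function(r)
      cbind(rep = r, report$stability[[r]])))
    utils::write.table(st, file.path(dir, "stability.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
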