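#' Canonical refinement of a representative structure
#'
#' Runs `n_traj` independent canonical trajectories at `T` from the
#' representative configuration with the docking-era restraints removed
#' (bonded and nonbonded terms are kept), pools the final `final_fraction`
#' of each surviving trajectory, and returns the pooled frame nearest (by
#' ligand-bead RMSD in the receptor frame; the toy receptor scaffold is
#' space-fixed, so this is the lab frame) to the pooled mean coordinates.
#' The production convention "final 40 ns of 100 ns" generalizes to the
#' final 40% of each trajectory.
#'
#' Trajectories that diverge are excluded with a warning; at least half must
#' survive.
#'
#' @param rep_coords `n x 3` representative configuration (or a snapshot
#'   row from an ensemble, reshaped automatically).
#' @param system the [toy_system()] to simulate.
#' @param n_traj number of trajectories (default 10).
#' @param T refinement temperature in K (default 300).
#' @param n_sweeps sweeps per trajectory.
#' @param seed base seed; per-trajectory seeds derive from it.
#' @param final_fraction tail fraction pooled (default 0.4).
#' @param save_every,step sampler settings.
#' @return An object of class `refined_rep`: list with `coords` (the
#'   refined configuration q), `energy`, `source_coords`, `n_surviving`,
#'   `run` (the pooled tail ensemble).
#' @export
refine_representative <- function(rep_coords, system, n_traj = 10, T = 300,
                                  n_sweeps = 4000, seed = 1,
                                  final_fraction = 0.4, save_every = 5,
                                  step = 0.25) {
  x0 <- .as_coords(rep_coords, system$n)
  sys <- system
  sys$restraints <- list()
  runs <- list()
  for (tr in seq_len(n_traj)) {
    r <- tryCatch(
      run_canonical(sys, T, n_sweeps, seed + 131 * tr,
                    save_every = save_every, step = step, coords0 = x0),
      error = function(e) NULL)
    if (is.null(r)) next
    tail_from <- floor((1 - final_fraction) * n_snapshots(r)) + 1
    runs[[length(runs) + 1]] <- r[tail_from:n_snapshots(r)]
  }
  if (length(runs) < ceiling(n_traj / 2)) {
    stop("fewer than half of the refinement trajectories survived (",
         length(runs), "/", n_traj, ")")
  }
  if (length(runs) < n_traj) {
    warning(n_traj - length(runs), " divergent trajectory(ies) excluded")
  }
  pooled <- bind_ensembles(runs)
  lig <- which(sys$chain_roles[sys$chains] == "ligand")
  cols <- as.vector(t(outer(3 * (lig - 1), 1:3, `+`)))
  mean_coords <- colMeans(pooled$coords)
  dev <- sweep(pooled$coords[, cols, drop = FALSE], 2, mean_coords[cols])
  rms <- sqrt(rowSums(dev^2) / length(lig))
  best <- which.min(rms)
  q <- matrix(pooled$coords[best, ], ncol = 3, byrow = TRUE)
  structure(list(coords = q, energy = pooled$energy[best],
                 source_coords = x0, n_surviving = length(runs),
                 run = pooled),
            class = "refined_rep")
}

.as_coords <- function(x, n) {
  if (is.matrix(x) && ncol(x) == 3) return(x)
  matrix(as.numeric(x), ncol = 3, byrow = TRUE)
}

#' Two-temperature stability score of a binding configuration
#'
#' Runs `n_traj` canonical trajectories at each probe temperature from the
#' representative, computes per trajectory the mean R-value of the final
#' tail frames against the initial representative structure (the
#' reference), and reports the mean and standard deviation across
#' trajectories per temperature — the standard relative-stability probe
#' comparing, e.g., 300 K and 400 K behavior of each binding configuration.
#'
#' @param rep_coords representative configuration.
#' @param system the [toy_system()] (restraints are removed for the runs).
#' @param temps probe temperatures in K.
#' @param n_traj trajectories per temperature (default 10).
#' @param n_sweeps sweeps per trajectory.
#' @param seed base seed (paired across temperatures, so the same seeds
#'   probe both).
#' @param final_fraction tail fraction scored.
#' @param scope,cutoff contact definition for the R-value.
#' @param save_every,step sampler settings.
#' @return Data frame (class `stability_report`) with `T`, `mean_r`,
#'   `sd_r`, `n_traj`.
#' @export
stability_score <- function(rep_coords, system, temps = c(300, 400),
                            n_traj = 10, n_sweeps = 2000, seed = 1,
                            final_fraction = 0.4, scope = "inter",
                            cutoff = 4.5, save_every = 5, step = 0.25) {
  x0 <- .as_coords(rep_coords, system$n)
  sys <- system
  sys$restraints <- list()
  ref <- toy_structure(sys, x0)
  out <- data.frame()
  for (T in temps) {
    per_traj <- numeric(0)
    for (tr in seq_len(n_traj)) {
      r <- tryCatch(
        run_canonical(sys, T, n_sweeps, seed + 131 * tr,
                      save_every = save_every, step = step, coords0 = x0),
        error = function(e) NULL)
      if (is.null(r)) next
      tail_from <- floor((1 - final_fraction) * n_snapshots(r)) + 1
      frames <- tail_from:n_snapshots(r)
      rv <- vapply(frames, function(s) {
        tryCatch(r_value(snapshot_structure(r, s), ref, scope, cutoff),
                 error = function(e) 0)
      }, numeric(1))
      per_traj <- c(per_traj, mean(rv))
    }
    if (length(per_traj) < ceiling(n_traj / 2)) {
      stop("fewer than half of the stability trajectories survived at T = ", T)
    }
    out <- rbind(out, data.frame(T = T, mean_r = mean(per_traj),
                                 sd_r = stats::sd(per_traj),
                                 n_traj = length(per_traj)))
  }
  structure(out, class = c("stability_report", "data.frame"))
}

#' @export
print.stability_report <- function(x, ...) {
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  %g K: R = %.3f (%.3f), n = %d\n", x$T[k], x$mean_r[k],
                x$sd_r[k], x$n_traj[k]))
  }
  invisible(x)
}
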