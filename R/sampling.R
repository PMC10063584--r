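#' Canonical Metropolis sampling of a toy system
#'
#' Runs single-particle Gaussian-move Metropolis Monte Carlo on the physical
#' potential at temperature `T`, which targets the canonical (Boltzmann)
#' distribution exactly. Identical seeds give bitwise-identical output; the
#' generator is internal to the kernel, so R's RNG state is untouched.
#'
#' @param system a [toy_system()].
#' @param T temperature in K (> 0).
#' @param n_sweeps number of Monte Carlo sweeps (one attempted move per
#'   mobile particle per sweep).
#' @param seed integer seed.
#' @param save_every sweeps between saved frames.
#' @param step Gaussian proposal standard deviation (Angstrom).
#' @param coords0 starting configuration (defaults to the system reference).
#' @param quench if `TRUE`, only downhill moves are accepted (zero-
#'   temperature descent mode); energies are then non-increasing.
#' @return An [ensemble()] with the saved frames and their energies.
#' @export
run_canonical <- function(system, T, n_sweeps, seed = 1, save_every = 5,
                          step = 0.25, coords0 = system$coords0,
                          quench = FALSE) {
  if (!quench && T <= 0) stop("temperature must be positive")
  run_mcmd(system, bias_identity(max(T, 1)), n_sweeps, seed,
           save_every = save_every, step = step, coords0 = coords0,
           quench = quench)
}

#' Multicanonical Metropolis sampling of a toy system
#'
#' Samples the modified energy `E_mc(E)` of `bias` at its sampling
#' temperature `T_mc`. With a converged bias the potential-energy histogram
#' is flat over the bias's fitted range; with [bias_identity()] this is
#' exactly canonical sampling. `n_parallel` independent trajectories are run
#' from per-trajectory seeds derived deterministically from `seed` and the
#' trajectory index and concatenated (trajectory ids retained).
#'
#' Energy excursions beyond the fitted bias range are legal — the mapping
#' continues linearly — and are counted in the returned metadata.
#'
#' @inheritParams run_canonical
#' @param bias a [bias_function()].
#' @param n_parallel number of independent trajectories.
#' @return An [ensemble()]; metadata records `T_mc`, the bias id, the save
#'   interval, per-trajectory acceptance rates and the out-of-range frame
#'   count.
#' @export
run_mcmd <- function(system, bias, n_sweeps, seed = 1, n_parallel = 1,
                     save_every = 5, step = 0.25, coords0 = system$coords0,
                     quench = FALSE) {
  if (n_sweeps < save_every) stop("n_sweeps must be at least save_every")
  runs <- vector("list", n_parallel)
  acc <- numeric(n_parallel)
  for (tr in seq_len(n_parallel)) {
    child_seed <- (abs(seed) * 1000003 + tr * 7919) %% 2147483647
    res <- .mc_sample_cpp(as.matrix(coords0),
                          system$mobile, system$masses,
                          system$terms$bonds, system$terms$pairs,
                          system$terms$dwells, system$terms$harm,
                          .fb_restraint_table(system),
                          .com_restraint_list(system),
                          if (is_identity_bias(bias)) numeric(0) else bias$E_grid,
                          if (is_identity_bias(bias)) numeric(0) else bias$E_mc,
                          bias$T_mc, as.integer(n_sweeps),
                          as.integer(save_every), step, child_seed, quench)
    if (!all(is.finite(res$energy))) {
      stop("divergent energies (non-finite) in trajectory ", tr,
           "; reduce the step size or check the potential terms")
    }
    acc[tr] <- res$acceptance
    runs[[tr]] <- ensemble(res$coords, res$energy, system,
                           traj = rep(tr, nrow(res$coords)))
  }
  out <- if (n_parallel == 1) runs[[1]] else bind_ensembles(runs)
  oor <- if (is_identity_bias(bias)) 0L else
    sum(out$energy < bias$E_range[1] | out$energy > bias$E_range[2])
  out$metadata <- list(T_mc = bias$T_mc, bias_id = bias$id,
                       save_interval = save_every, acceptance = acc,
                       n_out_of_range = oor, seed = seed)
  out
}

# restraints flattened for the kernel
.fb_restraint_table <- function(system) {
  fb <- Filter(function(r) r$kind == "flat_bottom_distance", system$restraints)
  if (length(fb) == 0) return(matrix(0, 0, 5))
  do.call(rbind, lapply(fb, function(r) c(r$i, r$j, r$lo, r$hi, r$k)))
}

.com_restraint_list <- function(system) {
  cb <- Filter(function(r) r$kind == "com_axis_box", system$restraints)
  lapply(cb, function(r) list(group = as.integer(r$group), axis = r$axis,
                              lo = r$lo, hi = r$hi, k = r$k))
}

#' Energy minimization by zero-temperature descent
#'
#' Convenience wrapper: a quench run followed by local gradient descent
#' polishing with [toy_gradient()].
#'
#' @inheritParams run_canonical
#' @param polish_steps gradient-descent polishing iterations.
#' @param lr descent step (A^2 mol/kcal).
#' @return List with `coords` (minimized configuration) and `energy`.
#' @export
minimize_toy <- function(system, coords0 = system$coords0, n_sweeps = 2000,
                         seed = 1, step = 0.1, polish_steps = 200, lr = 5e-3) {
  q <- run_canonical(system, T = 1, n_sweeps = n_sweeps, seed = seed,
                     save_every = n_sweeps, step = step, coords0 = coords0,
                     quench = TRUE)
  x <- matrix(q$coords[nrow(q$coords), ], ncol = 3, byrow = TRUE)
  for (i in seq_len(polish_steps)) {
    g <- toy_gradient(system, x) * system$mobile
    x <- x - lr * g
  }
  list(coords = x, energy = toy_energy(system, x))
}
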