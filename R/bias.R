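#' Multicanonical bias function
#'
#' A bias function is the modified-energy mapping `E -> E_mc(E)` that the
#' multicanonical sampler applies at its sampling temperature `T_mc`. It is
#' stored as a grid of energies with the mapped values; between grid points
#' the mapping is linear and beyond the grid it continues linearly with the
#' end-segment slopes, so it is defined (and monotone) everywhere. The ideal
#' mapping is `E_mc(E) = R * T_mc * ln n(E)` (`n` = density of states), for
#' which sampling `exp(-E_mc/(R*T_mc))` yields a flat energy histogram.
#'
#' @param E_grid ascending energy grid (kcal/mol).
#' @param E_mc mapped energies on the grid.
#' @param T_mc sampling temperature (K).
#' @param E_range valid (fitted) energy range; defaults to the grid range.
#' @return An object of class `bias_function`.
#' @export
bias_function <- function(E_grid, E_mc, T_mc, E_range = range(E_grid)) {
  if (length(E_grid) != length(E_mc)) stop("grid length mismatch")
  if (is.unsorted(E_grid, strictly = TRUE)) stop("E_grid must be strictly increasing")
  if (any(diff(E_mc) < -1e-9)) stop("E_mc must be monotone non-decreasing")
  if (T_mc <= 0) stop("T_mc must be positive")
  structure(list(E_grid = E_grid, E_mc = E_mc, T_mc = T_mc,
                 E_range = E_range,
                 id = sprintf("bias-%08x", bitwAnd(
                   as.integer(sum(E_mc * 1e3) %% 2^28), 268435455L))),
            class = "bias_function")
}

#' Identity bias (canonical sampling)
#'
#' With the identity mapping the multicanonical sampler reduces exactly to a
#' canonical sampler at `T_mc`.
#'
#' @param T_mc sampling temperature (K).
#' @export
bias_identity <- function(T_mc) {
  structure(list(E_grid = NULL, E_mc = NULL, T_mc = T_mc, E_range = c(-Inf, Inf),
                 id = "identity"), class = "bias_function")
}

is_identity_bias <- function(bias) is.null(bias$E_grid)

#' Evaluate a bias function
#'
#' Linear interpolation on the stored grid with linear extensions outside it
#' (identical to the sampler kernel's evaluation).
#'
#' @param bias a [bias_function()].
#' @param E numeric vector of energies.
#' @return `E_mc(E)`.
#' @export
bias_value <- function(bias, E) {
  if (is_identity_bias(bias)) return(E)
  g <- bias$E_grid; v <- bias$E_mc; n <- length(g)
  out <- stats::approx(g, v, xout = pmin(pmax(E, g[1]), g[n]))$y
  lo <- E < g[1]; hi <- E > g[n]
  if (any(lo)) out[lo] <- v[1] + (v[2] - v[1]) / (g[2] - g[1]) * (E[lo] - g[1])
  if (any(hi)) out[hi] <- v[n] + (v[n] - v[n - 1]) / (g[n] - g[n - 1]) * (E[hi] - g[n])
  out
}

#' @export
print.bias_function <- function(x, ...) {
  if (is_identity_bias(x)) {
    cat(sprintf("bias_function: identity (canonical at %g K)\n", x$T_mc))
  } else {
    cat(sprintf("bias_function: %d knots on [%.3g, %.3g] kcal/mol, T_mc = %g K\n",
                length(x$E_grid), x$E_range[1], x$E_range[2], x$T_mc))
  }
  invisible(x)
}

#' Configuration of the multicanonical iteration
#'
#' @param T_low,T_high temperature range (K) the flat energy histogram should
#'   span; defaults follow the wide production range 280-700 K.
#' @param bin_width energy histogram bin width (kcal/mol).
#' @param flatness_tol convergence threshold on the max/min histogram-count
#'   ratio over the target energy range (1.2 = within 20%).
#' @param init_sweeps sweeps of the seeding canonical run at `T_high`.
#' @param schedule sweeps per bias-update iteration (recycled if the
#'   iteration count exceeds its length).
#' @param max_iter maximum bias updates.
#' @param n_parallel number of independent trajectories per run.
#' @param save_every sweeps between saved frames.
#' @param step Metropolis step size (Angstrom).
#' @return A list of class `mcmd_config`.
#' @export
mcmd_config <- function(T_low = 280, T_high = 700, bin_width = 0.5,
                        flatness_tol = 1.2, init_sweeps = 2e5,
                        schedule = c(2e5, 2e5, 4e5, 4e5, 8e5),
                        max_iter = 8, n_parallel = 1, save_every = 2,
                        step = 0.35) {
  if (T_low >= T_high) stop("T_low must be below T_high")
  if (any(c(init_sweeps, schedule) <= 0)) stop("all run lengths must be positive")
  structure(list(T_low = T_low, T_high = T_high, bin_width = bin_width,
                 flatness_tol = flatness_tol, init_sweeps = init_sweeps,
                 schedule = schedule, max_iter = max_iter,
                 n_parallel = n_parallel, save_every = save_every,
                 step = step), class = "mcmd_config")
}

# Histogram of energies on a fixed bin width; returns centers and counts.
energy_histogram <- function(E, bin_width) {
  lo <- floor(min(E) / bin_width) * bin_width
  hi <- ceiling(max(E) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  if ((hi - lo) / bin_width > 2e5) {
    stop("energy range spans more than 2e5 histogram bins; ",
         "the run has likely diverged or the bin width is too small")
  }
  edges <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(E, breaks = edges, plot = FALSE)$counts
  list(centers = (edges[-1] + edges[-length(edges)]) / 2, counts = counts,
       edges = edges)
}

#' Flattening update of a multicanonical bias
#'
#' Adds `R * T_mc * ln P_obs(E)` (smoothed) to the modified energy, so that
#' over-sampled energies are penalized on the next run. A flat observed
#' histogram therefore returns the input bias up to an additive constant.
#' Empty bins inside the occupied range are bridged by interpolation with a
#' warning. Monotonicity of `E_mc` is enforced after smoothing.
#'
#' Outside the canonical mean-energy range `[<E>(T_low), <E>(T_high)]`
#' (estimated by reweighting the production run under the current bias) the
#' mapping is continued with the canonical tail slopes `T_mc/T_low` below
#' and `T_mc/T_high` above, so sampling beyond the target range falls off
#' like a canonical ensemble at the corresponding limit temperature instead
#' of random-walking to extreme energies.
#'
#' @param bias the current [bias_function()] (use [bias_identity()] with
#'   `T_mc = T_high` for the first estimate).
#' @param production [ensemble()] generated under `bias`.
#' @param cfg an [mcmd_config()].
#' @param smooth_df effective degrees of freedom of the smoothing spline
#'   applied to `ln P_obs`; the default (`NULL`) uses 70% of the occupied
#'   bin count — enough flexibility to follow the log-density while damping
#'   per-bin sampling noise.
#' @return The updated [bias_function()].
#' @export
update_bias <- function(bias, production, cfg, smooth_df = NULL) {
  E <- production$energy
  h <- energy_histogram(E, cfg$bin_width)
  occupied <- h$counts > 0
  if (sum(occupied) < 5) {
    stop("too few distinct energy bins (", sum(occupied),
         "); run a longer seed simulation")
  }
  inner <- seq(which(occupied)[1], max(which(occupied)))
  if (any(!occupied[inner])) {
    warning(sum(!occupied[inner]),
            " empty energy bin(s) inside the sampled range bridged by interpolation")
  }
  lnP <- rep(NA_real_, length(h$centers))
  lnP[occupied] <- log(h$counts[occupied] / sum(h$counts))
  lnP <- lnP[inner]
  centers <- h$centers[inner]
  # bridge interior gaps, then smooth
  if (anyNA(lnP)) lnP <- stats::approx(centers[!is.na(lnP)], lnP[!is.na(lnP)],
                                       xout = centers)$y
  w <- pmax(h$counts[inner], 1)
  if (is.null(smooth_df)) smooth_df <- max(10, floor(0.7 * length(centers)))
  df <- min(smooth_df, length(centers) - 1)
  sm <- if (length(centers) >= 8) {
    stats::predict(stats::smooth.spline(centers, lnP, w = w, df = df),
                   centers)$y
  } else lnP
  T_mc <- bias$T_mc
  e_mc <- bias_value(bias, centers) + GAS_CONSTANT * T_mc * sm
  e_mc <- cummax(e_mc)  # keep E -> E_mc monotone
  # canonical tail slopes outside the target mean-energy range
  E_hi <- sum(canonical_weights(production, bias, cfg$T_high)$w * E)
  E_lo <- suppressWarnings(
    sum(canonical_weights(production, bias, cfg$T_low)$w * E))
  i_lo <- max(1, findInterval(E_lo, centers))
  i_hi <- min(length(centers), findInterval(E_hi, centers) + 1)
  if (i_lo > 1) {
    s_lo <- T_mc / cfg$T_low
    e_mc[1:(i_lo - 1)] <- e_mc[i_lo] - s_lo * (centers[i_lo] - centers[1:(i_lo - 1)])
  }
  if (i_hi < length(centers)) {
    s_hi <- T_mc / cfg$T_high
    e_mc[(i_hi + 1):length(centers)] <-
      e_mc[i_hi] + s_hi * (centers[(i_hi + 1):length(centers)] - centers[i_hi])
  }
  e_mc <- cummax(e_mc)
  bias_function(centers, e_mc - min(e_mc), T_mc,
                E_range = c(E_lo, E_hi))
}

#' Initial bias estimate from a high-temperature canonical run
#'
#' From a canonical run at `T_high`, `ln n(E) = ln P(E) + E/(R*T_high)` up to
#' a constant, so the first multicanonical estimate is the identity mapping
#' plus the flattening correction `R * T_high * ln P(E)` — one
#' [update_bias()] step on the identity bias.
#'
#' @param canonical_run [ensemble()] sampled canonically at `cfg$T_high`.
#' @param cfg an [mcmd_config()].
#' @return A [bias_function()] with `T_mc = cfg$T_high`.
#' @export
estimate_initial_bias <- function(canonical_run, cfg) {
  update_bias(bias_identity(cfg$T_high), canonical_run, cfg)
}

#' Histogram flatness over a target energy range
#'
#' Ratio of the maximum to the minimum bin count of the energy histogram,
#' restricted to `[E_lo, E_hi]`. 1 is perfectly flat.
#'
#' @param E sampled energies.
#' @param E_lo,E_hi target range bounds (kcal/mol).
#' @param bin_width histogram bin width.
#' @return The max/min count ratio (`Inf` if a bin in range is empty).
#' @export
flatness_ratio <- function(E, E_lo, E_hi, bin_width = 0.5) {
  h <- energy_histogram(E, bin_width)
  sel <- h$centers >= E_lo & h$centers <= E_hi
  if (!any(sel)) return(Inf)
  cnt <- h$counts[sel]
  if (min(cnt) == 0) return(Inf)
  max(cnt) / min(cnt)
}

#' Iterative multicanonical bias flattening
#'
#' Full production protocol: a canonical seed run at `T_high`, an initial
#' bias estimate, then multicanonical runs of increasing length with a
#' flattening update after each, until the energy histogram is flat (to
#' `cfg$flatness_tol`) over the canonical mean-energy range
#' `[<E>(T_low), <E>(T_high)]` — both means estimated by reweighting the
#' current run — or `cfg$max_iter` updates have been spent.
#'
#' @param system a [toy_system()].
#' @param cfg an [mcmd_config()].
#' @param seed integer base seed.
#' @return List with elements `bias`, `run` (the last multicanonical run),
#'   `flatness` (trace of per-iteration ratios), `target_range`,
#'   `n_iterations` and `converged`.
#' @export
iterate_bias <- function(system, cfg = mcmd_config(), seed = 1) {
  seed_run <- run_canonical(system, cfg$T_high, cfg$init_sweeps, seed,
                            save_every = cfg$save_every, step = cfg$step)
  bias <- estimate_initial_bias(seed_run, cfg)
  flat_trace <- numeric(0)
  run <- NULL
  target <- c(NA_real_, NA_real_)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    sweeps <- cfg$schedule[min(it, length(cfg$schedule))]
    run <- run_mcmd(system, bias, sweeps, seed + it,
                    n_parallel = cfg$n_parallel,
                    save_every = cfg$save_every, step = cfg$step)
    w_lo <- canonical_weights(run, bias, cfg$T_low)
    w_hi <- canonical_weights(run, bias, cfg$T_high)
    target <- c(sum(w_lo$w * run$energy), sum(w_hi$w * run$energy))
    fr <- flatness_ratio(run$energy, target[1], target[2], cfg$bin_width)
    flat_trace <- c(flat_trace, fr)
    if (fr <= cfg$flatness_tol) { converged <- TRUE; break }
    bias <- update_bias(bias, run, cfg)
  }
  list(bias = bias, run = run, flatness = flat_trace, target_range = target,
       n_iterations = length(flat_trace), converged = converged)
}
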