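#' Double-well toy system with a quadrature oracle
#'
#' One particle in a quartic double well along x,
#' `U(x) = barrier * ((x^2 - w^2)/w^2)^2 + slope * x` with minima near
#' `x = -w` and `x = +w` (`w` = 1.5 Angstrom) and the right well raised by
#' `asymmetry` kcal/mol; `dims = 2` adds an independent harmonic y term
#' (`k_y = 1`). The returned oracle computes canonical properties by direct
#' numerical quadrature — independent of the sampling machinery — and is
#' the reference every sampler/reweighting result is checked against.
#'
#' Default energy scales put the barrier at roughly 5-10 times `R*T` at 280
#' K, so the 280-700 K range spans rare-to-frequent barrier crossing, the
#' regime multicanonical sampling is designed for.
#'
#' @param barrier barrier height in kcal/mol (> 0).
#' @param asymmetry energy offset of the right well in kcal/mol.
#' @param dims 1 or 2.
#' @return List with `system` (a [toy_system()]) and `oracle` (see
#'   Details). The oracle provides `U(x[, y])`, `mean_energy(T)`,
#'   `energy_cdf(T)` (a function of E), `population_right(T)` and
#'   `pmf2d(xedges, yedges, T)`.
#' @export
make_double_well <- function(barrier = 4, asymmetry = 1, dims = 1) {
  if (barrier <= 0) stop("barrier must be positive")
  w <- 1.5
  slope <- asymmetry / (2 * w)
  k_y <- 1
  mobile <- matrix(0, 1, 3)
  mobile[1, 1] <- 1
  terms <- list(dwells = matrix(c(1, 1, barrier, 0, w, slope), 1, 6))
  if (dims == 2) {
    mobile[1, 2] <- 1
    terms$harm <- matrix(c(1, 2, k_y, 0), 1, 4)
  } else if (dims != 1) stop("dims must be 1 or 2")
  sys <- toy_system(coords0 = matrix(c(-w, 0, 0), 1, 3), masses = 12,
                    mobile = mobile, chains = "L", terms = terms)

  Ux <- function(x) barrier * ((x^2 - w^2) / w^2)^2 + slope * x
  U <- if (dims == 2) function(x, y) Ux(x) + k_y * y^2 else function(x, y = 0) Ux(x)
  xg <- seq(-4 * w, 4 * w, length.out = 8001)
  yg <- if (dims == 2) seq(-6, 6, length.out = 401) else 0
  grid_weights <- function(T) {
    if (dims == 1) {
      u <- Ux(xg)
      list(u = u, p = exp(-(u - min(u)) / (GAS_CONSTANT * T)))
    } else {
      g <- expand.grid(x = xg, y = yg)
      u <- U(g$x, g$y)
      list(u = u, p = exp(-(u - min(u)) / (GAS_CONSTANT * T)), x = g$x)
    }
  }
  oracle <- list(
    U = U,
    w = w,
    mean_energy = function(T) {
      gw <- grid_weights(T)
      sum(gw$u * gw$p) / sum(gw$p)
    },
    energy_cdf = function(T) {
      gw <- grid_weights(T)
      ord <- order(gw$u)
      u <- gw$u[ord]
      cw <- cumsum(gw$p[ord]) / sum(gw$p)
      function(E) stats::approx(u, cw, xout = E, yleft = 0, yright = 1,
                                ties = "ordered")$y
    },
    population_right = function(T) {
      gw <- grid_weights(T)
      xs <- if (dims == 1) xg else gw$x
      sum(gw$p[xs > 0]) / sum(gw$p[xs != 0])  # x = 0 belongs to neither well
    },
    pmf2d = function(xedges, yedges, T, subdiv = 8) {
      # per-bin -RT ln integral of the Boltzmann factor, by sub-grid sums
      nx <- length(xedges) - 1; ny <- length(yedges) - 1
      P <- matrix(0, nx, ny)
      for (i in seq_len(nx)) {
        xs <- seq(xedges[i], xedges[i + 1], length.out = subdiv)
        for (j in seq_len(ny)) {
          ys <- seq(yedges[j], yedges[j + 1], length.out = subdiv)
          g <- expand.grid(x = xs, y = ys)
          P[i, j] <- mean(exp(-U(g$x, g$y) / (GAS_CONSTANT * T))) *
            diff(xedges[i:(i + 1)]) * diff(yedges[j:(j + 1)])
        }
      }
      pmf <- -GAS_CONSTANT * T * log(P / sum(P))
      pmf - min(pmf)
    })
  list(system = sys, oracle = oracle)
}

#' Cryptic-pocket binding toy system
#'
#' A coarse-grained stand-in for coupled folding and binding at a cryptic
#' site. A space-fixed receptor scaffold carries four attraction sites
#' (analogs of sub-pockets P1-P4) in a groove along the x axis, with P1 the
#' innermost and P4 the outermost (bulk-accessible) site. A mobile gate bead
#' over the inner groove (P1-P3) lives in a double-well along y whose closed
#' state (over the groove) is lower by `gate_bias` when the pocket is empty;
#' the closed gate sterically repels the three inner ligand beads while P4
#' stays accessible in either gate state, so pocket occupancy and gate
#' opening are thermodynamically coupled and binding is funneled to initiate
#' at the P4 analog. The ligand is a bead chain with
#' weak intrinsic stiffness (1-3 springs) that is disordered when free; the
#' collinear, evenly spaced sites force the chain straight ("folded") when
#' bound, so binding and folding are coupled too. `coupling` scales all
#' receptor-ligand nonbonded terms: at `coupling = 0` the ligand never
#' feels the receptor (degenerate null system, allowed with a warning;
#' negative values are rejected).
#'
#' The center of mass of the ligand is restrained to the dissociation range
#' `lambda` in `[-2.5, 40]` Angstrom along x (force constant 10
#' kcal/mol/A^2) and loosely boxed in y/z.
#'
#' @param n_ligand_beads ligand chain length (>= 4).
#' @param gate_bias closed-state preference of the empty gate (kcal/mol,
#'   > 0).
#' @param coupling receptor-ligand interaction scale (kcal/mol, >= 0).
#' @param seed unused at construction (geometry is deterministic); kept so
#'   generator calls are uniform.
#' @return List with `system` and `oracle`. The oracle carries the planted
#'   truth: site positions, `gate_open(y)`/`gate_closed(y)` classifiers,
#'   `bound(lambda)` (lambda below `lambda_bound_threshold`),
#'   `is_folded(coords)` and `bound_coords`/`unbound_coords` reference
#'   configurations, plus `global_minimum_is_bound_open_folded(system)`
#'   which verifies the planted minimum by quenching from alternatives.
#' @export
make_cryptic_toy <- function(n_ligand_beads = 6, gate_bias = 1.5,
                             coupling = 3, seed = 1) {
  if (n_ligand_beads < 4) stop("need at least 4 ligand beads")
  if (gate_bias <= 0) stop("gate_bias must be positive (closed state favored)")
  if (coupling < 0) stop("coupling must be non-negative")
  if (coupling == 0) {
    warning("coupling = 0: degenerate system, ligand does not feel the receptor")
  }
  r0 <- 2                       # bond length and site spacing (Angstrom)
  site_x <- c(1, 3, 5, 7)       # P1..P4 along the groove
  gate_m <- 2.7; gate_w <- 1.5  # gate double-well: closed y=1.2, open y=4.2
  n_l <- n_ligand_beads
  rec <- rbind(cbind(site_x, 0, 0),            # P1..P4 site beads (fixed)
               c(3, gate_m - gate_w, 0))       # gate bead over the inner groove
  gate_i <- nrow(rec)
  lig0 <- cbind(site_x[1] + r0 * (seq_len(n_l) - 1), 0, 0)  # bound reference
  coords0 <- rbind(rec, lig0)
  lig_i <- gate_i + seq_len(n_l)
  mobile <- matrix(0, nrow(coords0), 3)
  mobile[gate_i, 2] <- 1                        # gate moves along y only
  mobile[lig_i, ] <- 1
  bonds <- NULL
  for (b in seq_len(n_l - 1)) {
    bonds <- rbind(bonds, c(lig_i[b], lig_i[b + 1], 10, r0))
  }
  for (b in seq_len(n_l - 2)) {                 # weak stiffness (1-3 springs)
    bonds <- rbind(bonds, c(lig_i[b], lig_i[b + 2], 0.3, 2 * r0))
  }
  pairs <- NULL
  for (s in 1:4) {                              # bead s binds site s
    pairs <- rbind(pairs, c(s, lig_i[s], -coupling, 1.0))
  }
  for (b in 1:3) {  # closed gate fully neutralizes the inner sub-pockets:
    # the steric penalty at an occupied inner site matches or exceeds the
    # site well depth, so only P4 is attractive while the gate is shut
    pairs <- rbind(pairs, c(gate_i, lig_i[b], 2 * coupling, 2.0))
  }
  dwells <- matrix(c(gate_i, 2, 3, gate_m, gate_w,
                     gate_bias / (2 * gate_w)), 1, 6)
  restraints <- list(
    restraint_spec("com_axis_box", group = lig_i, lo = -2.5, hi = 40,
                   k = 10, axis = 1),
    restraint_spec("com_axis_box", group = lig_i, lo = -8, hi = 8,
                   k = 10, axis = 2),
    restraint_spec("com_axis_box", group = lig_i, lo = -8, hi = 8,
                   k = 10, axis = 3))
  sys <- toy_system(coords0, masses = 12, mobile = mobile,
                    chains = c(rep("R", gate_i), rep("L", n_l)),
                    chain_roles = c(R = "receptor", L = "ligand"),
                    terms = list(bonds = bonds, pairs = pairs,
                                 dwells = dwells),
                    restraints = restraints,
                    names = c(sprintf("P%d", 1:4), "GATE",
                              sprintf("L%d", seq_len(n_l))))

  unbound <- coords0
  unbound[lig_i, 1] <- unbound[lig_i, 1] + 20   # shifted into the bulk
  oracle <- list(
    site_x = site_x, gate_index = gate_i, ligand_index = lig_i,
    gate_open_y = gate_m + gate_w, gate_closed_y = gate_m - gate_w,
    gate_is_open = function(y) y > gate_m,
    lambda_bound_threshold = 12,
    bound = function(lambda) lambda < 12,
    is_folded = function(coords) {
      d13 <- sqrt(rowSums((coords[lig_i[-(1:2)], , drop = FALSE] -
                             coords[lig_i[seq_len(n_l - 2)], , drop = FALSE])^2))
      all(d13 > 0.8 * 2 * r0)
    },
    bound_coords = coords0, unbound_coords = unbound,
    global_minimum_is_bound_open_folded = function(system, seed = 1) {
      open_bound <- coords0; open_bound[gate_i, 2] <- gate_m + gate_w
      starts <- list(open_bound, coords0, unbound)
      mins <- lapply(seq_along(starts), function(k)
        minimize_toy(system, starts[[k]], seed = seed + k))
      best <- which.min(vapply(mins, `[[`, numeric(1), "energy"))
      x <- mins[[best]]$coords
      lam <- sum(x[lig_i, 1]) / n_l
      list(is_bound = lam < 12,
           is_open = x[gate_i, 2] > gate_m,
           is_folded = {
             d13 <- sqrt(rowSums((x[lig_i[-(1:2)], , drop = FALSE] -
                                    x[lig_i[seq_len(n_l - 2)], , drop = FALSE])^2))
             all(d13 > 0.8 * 2 * r0)
           },
           energy = mins[[best]]$energy)
    })
  list(system = sys, oracle = oracle)
}

#' Per-bead fold labels for toy ligand chains
#'
#' The toy analog of a secondary-structure labeller: an interior ligand
#' bead is "helical" (`H`) when the 1-3 distance across it exceeds 80% of
#' the straight-chain value (the chain is locally extended rather than
#' collapsed); terminal beads and receptor beads are `C`.
#' Compatible with [helicity_profile()] as its `labeller`.
#'
#' @param model a [toy_structure()] rendering of a toy snapshot.
#' @param r0 chain bond length (Angstrom).
#' @return Named label vector as in [assign_ss()].
#' @export
toy_fold_labels <- function(model, r0 = 2) {
  a <- model$atoms
  out <- character(0)
  for (ch in names(model$chain_roles)) {
    rows <- which(a$chain == ch)
    n <- length(rows)
    lab <- rep("C", n)
    if (model$chain_roles[[ch]] == "ligand" && n >= 3) {
      xyz <- as.matrix(a[rows, c("x", "y", "z")])
      d13 <- sqrt(rowSums((xyz[3:n, , drop = FALSE] -
                             xyz[1:(n - 2), , drop = FALSE])^2))
      lab[2:(n - 1)][d13 > 0.8 * 2 * r0] <- "H"
    }
    names(lab) <- sprintf("%s:%d", ch, a$resid[rows])
    out <- c(out, lab)
  }
  out
}

#' Planted multi-modal ensemble with known cluster weights
#'
#' Draws `n` snapshots from a set of binding-configuration modes with known
#' canonical masses, arranged so that reweighting genuinely matters: modes
#' are sampled with equal counts (a flat, multicanonical-like occupancy) and
#' each mode's snapshots carry a constant energy chosen so that canonical
#' reweighting of the (identity-bias, `T_mc` = 700 K) ensemble to 300 K
#' recovers the planted masses. Each mode is a distinct assignment of
#' ligand beads to well-separated receptor anchor positions, realized as
#' coordinates; the fraction of shared assignments between two modes is
#' exactly their mutual contact similarity (R-value), so merge behavior is
#' controllable by construction.
#'
#' @param mode_spec list of modes, each a list with `mass` (canonical mass
#'   at 300 K; masses must sum to 1) and `assign` (integer vector mapping
#'   each ligand bead to a receptor anchor index; equal length across
#'   modes). `spread` (coordinate jitter sd, default 0.15) may be set per
#'   mode.
#' @param n total snapshot count (>= 10 per mode).
#' @param seed integer seed.
#' @param n_anchors number of receptor anchor positions (default: maximum
#'   assigned index).
#' @return List with `ensemble` (topology attached), `weights` (canonical
#'   `weight_vector` at 300 K), and `truth` (per-snapshot mode labels,
#'   planted masses, anchor geometry and pairwise planted contact overlap).
#' @export
make_planted_ensemble <- function(mode_spec, n = 600, seed = 1,
                                  n_anchors = NULL) {
  M <- length(mode_spec)
  masses <- vapply(mode_spec, `[[`, numeric(1), "mass")
  if (abs(sum(masses) - 1) > 1e-9) stop("mode masses must sum to 1")
  if (n < 10 * M) stop("need at least 10 snapshots per mode")
  assigns <- lapply(mode_spec, `[[`, "assign")
  L <- length(assigns[[1]])
  if (any(vapply(assigns, length, numeric(1)) != L)) {
    stop("all modes must assign the same number of ligand beads")
  }
  if (is.null(n_anchors)) n_anchors <- max(unlist(assigns))
  # receptor anchors far apart so contacts are unambiguous
  anchor_pos <- cbind(8 * (seq_len(n_anchors) - 1), 0, 0)
  T_mc <- 700; T_target <- 300
  cinv <- 1 / (GAS_CONSTANT * T_target) - 1 / (GAS_CONSTANT * T_mc)
  E_mode <- -log(masses) / cinv
  E_mode <- E_mode - min(E_mode)
  counts <- rep(n %/% M, M)
  counts[seq_len(n - sum(counts))] <- counts[seq_len(n - sum(counts))] + 1
  set.seed(seed)
  coords <- NULL; energy <- NULL; labels <- NULL
  for (m in seq_len(M)) {
    spread <- mode_spec[[m]]$spread %||% 0.15
    lig <- anchor_pos[assigns[[m]], , drop = FALSE]
    lig[, 2] <- lig[, 2] + 2.5   # ligand bead sits 2.5 A above its anchor
    for (s in seq_len(counts[m])) {
      jit <- matrix(stats::rnorm(3 * L, 0, spread), L, 3)
      frame <- rbind(anchor_pos, lig + jit)
      coords <- rbind(coords, as.vector(t(frame)))
      energy <- c(energy, E_mode[m] + stats::rnorm(1, 0, 0.005))
      labels <- c(labels, m)
    }
  }
  topo <- toy_system(rbind(anchor_pos, cbind(0, 2.5, 0)[rep(1, L), ] +
                             anchor_pos[assigns[[1]], , drop = FALSE]),
                     masses = 12, mobile = FALSE,
                     chains = c(rep("R", n_anchors), rep("L", L)),
                     chain_roles = c(R = "receptor", L = "ligand"))
  ens <- ensemble(coords, energy, topology = topo,
                  metadata = list(T_mc = T_mc, bias_id = "identity",
                                  save_interval = 1))
  wts <- canonical_weights(ens, bias_identity(T_mc), T_target)
  overlap <- outer(seq_len(M), seq_len(M), Vectorize(function(i, j)
    mean(assigns[[i]] == assigns[[j]])))
  list(ensemble = ens, weights = wts,
       truth = list(labels = labels, masses = masses, E_mode = E_mode,
                    assigns = assigns, anchor_pos = anchor_pos,
                    overlap = overlap))
}
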