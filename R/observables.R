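#' Secondary-structure assignment (Kabsch-Sander)
#'
#' Assigns per-residue secondary-structure classes from backbone geometry
#' using the Kabsch-Sander hydrogen-bond energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, with a
#' bond accepted below -0.5 kcal/mol. The amide hydrogen is positioned
#' geometrically (1 Angstrom from N along the preceding residue's C=O
#' direction) when absent. Classes:
#' * `H` — alpha-helix: residues `i..i+3` covered by two consecutive
#'   4-turns (H-bonds `CO(i-1)..NH(i+3)` and `CO(i)..NH(i+4)`);
#' * `G` — 3-10 helix, same rule with 3-turns, only where not already `H`;
#' * `E` — beta strand, residues in parallel or antiparallel bridges;
#' * `C` — everything else.
#' Terminal residues can never be `H` by the `i -> i+4` rule. Residues with
#' missing backbone atoms are labelled `C` with a warning.
#'
#' @param model a [structure_model()] with per-residue N, CA, C, O atoms.
#' @param chain optional chain id(s) to assign (default: all chains,
#'   each treated as a separate polymer).
#' @return Named character vector of labels, one per residue, names
#'   `"<chain>:<resid>"`.
#' @export
assign_ss <- function(model, chain = NULL) {
  a <- model$atoms
  chains <- if (is.null(chain)) names(model$chain_roles) else chain
  out <- character(0)
  for (ch in chains) {
    resids <- unique(a$resid[a$chain == ch])
    n <- length(resids)
    bb <- array(NA_real_, c(n, 4, 3),
                dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
    ok <- rep(TRUE, n)
    for (r in seq_len(n)) {
      for (at in c("N", "CA", "C", "O")) {
        row <- which(a$chain == ch & a$resid == resids[r] & a$name == at)
        if (length(row) == 0) { ok[r] <- FALSE; next }
        bb[r, at, ] <- as.numeric(a[row[1], c("x", "y", "z")])
      }
    }
    if (any(!ok)) {
      warning("residue(s) with missing backbone atoms labelled C in chain ", ch)
    }
    labels <- rep("C", n)
    if (n >= 3) {
      # amide H positions (none for residue 1 or after a gap)
      H <- matrix(NA_real_, n, 3)
      for (r in 2:n) {
        if (ok[r] && ok[r - 1]) {
          co <- bb[r - 1, "C", ] - bb[r - 1, "O", ]
          H[r, ] <- bb[r, "N", ] + co / sqrt(sum(co^2))
        }
      }
      # hbond[i, j]: TRUE when NH of donor i bonds CO of acceptor j
      hb <- matrix(FALSE, n, n)
      dd <- function(p, q) sqrt(sum((p - q)^2))
      for (i in 2:n) {
        if (!ok[i] || anyNA(H[i, ])) next
        for (j in seq_len(n)) {
          if (abs(i - j) < 2 || !ok[j]) next
          rON <- dd(bb[j, "O", ], bb[i, "N", ])
          if (rON > 5.2) next   # distance pre-screen, generous for |E|>0.5
          E <- 0.084 * 332 * (1 / rON + 1 / dd(bb[j, "C", ], H[i, ]) -
                                1 / dd(bb[j, "O", ], H[i, ]) -
                                1 / dd(bb[j, "C", ], bb[i, "N", ]))
          hb[i, j] <- E < -0.5
        }
      }
      turn <- function(len) {
        t <- rep(FALSE, n)
        for (i in seq_len(n - len)) t[i] <- hb[i + len, i]
        t
      }
      t4 <- turn(4); t3 <- turn(3)
      for (i in 2:n) {          # two consecutive 4-turns at i-1 and i
        if (i + 3 <= n && t4[i - 1] && t4[i]) labels[i:(i + 3)] <- "H"
      }
      # beta bridges (parallel / antiparallel); Hbond(a acceptor, b donor)
      hbd <- function(acc, don) acc >= 1 && acc <= n && don >= 1 && don <= n &&
        hb[don, acc]
      bridge <- rep(FALSE, n)
      for (i in 2:(n - 1)) {
        for (j in 2:(n - 1)) {
          if (abs(i - j) < 3) next
          para <- (hbd(i - 1, j) && hbd(j, i + 1)) ||
            (hbd(j - 1, i) && hbd(i, j + 1))
          anti <- (hbd(i, j) && hbd(j, i)) ||
            (hbd(i - 1, j + 1) && hbd(j - 1, i + 1))
          if (para || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
        }
      }
      labels[bridge & labels == "C"] <- "E"
      for (i in 2:n) {          # 3-10 helix where not already alpha
        if (i + 2 <= n && t3[i - 1] && t3[i]) {
          seg <- i:(i + 2)
          labels[seg][labels[seg] == "C"] <- "G"
        }
      }
    }
    labels[!ok] <- "C"   # incomplete residues are never assigned structure
    names(labels) <- sprintf("%s:%d", ch, resids)
    out <- c(out, labels)
  }
  out
}

#' Reweighted per-residue helix probability
#'
#' For each residue of the chosen chain, the summed canonical weight of the
#' snapshots in which the residue is labelled `H`. By the package's
#' documented convention "helicity" counts the alpha-helix class only (not
#' 3-10); pass `classes = c("H", "G")` for the broader reading.
#'
#' @param ens an [ensemble()] with a topology convertible to structures.
#' @param weights a `weight_vector`.
#' @param chain chain id to profile (default: first ligand chain).
#' @param classes secondary-structure classes counted as helical.
#' @param labeller function mapping a structure to per-residue labels;
#'   [assign_ss()] by default (toy ensembles supply their own, e.g.
#'   [toy_fold_labels()]).
#' @return Named numeric vector of per-residue helix probabilities in
#'   `[0, 1]`.
#' @export
helicity_profile <- function(ens, weights, chain = NULL, classes = "H",
                             labeller = assign_ss) {
  w <- if (inherits(weights, "weight_vector")) weights$w else weights
  first <- snapshot_structure(ens, 1)
  if (is.null(chain)) {
    lig <- names(first$chain_roles)[first$chain_roles == "ligand"]
    chain <- if (length(lig)) lig[1] else names(first$chain_roles)[1]
  }
  lab1 <- labeller(snapshot_structure(ens, 1))
  keep <- startsWith(names(lab1), paste0(chain, ":"))
  prof <- rep(0, sum(keep))
  names(prof) <- names(lab1)[keep]
  for (s in seq_len(n_snapshots(ens))) {
    lab <- labeller(snapshot_structure(ens, s))[keep]
    prof <- prof + w[s] * (lab %in% classes)
  }
  prof / sum(w)
}

# deterministic, nearly uniform sphere points (golden spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point accessibility with a deterministic golden-spiral point set:
#' each atom's sphere of radius `r_vdw + probe` is sampled at `n_points`
#' points; the accessible fraction is the share of points not inside any
#' other atom's expanded sphere. All atoms of the model occlude; areas are
#' reported for `selection`.
#'
#' @param model a [structure_model()].
#' @param selection atom indices to report (default: all atoms).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere points per atom.
#' @return An object of class `sasa_result`: list with per-atom `area`
#'   (named by atom id) and `total` (Angstrom^2).
#' @export
sasa <- function(model, selection = NULL, probe = 1.4, n_points = 960) {
  a <- model$atoms
  radii <- vdw_radii()[toupper(a$element)]
  if (anyNA(radii)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$element[is.na(radii)]), collapse = ", "))
  }
  if ("radius" %in% names(a)) {
    radii <- ifelse(is.na(a$radius), radii, a$radius)
  }
  if (is.null(selection)) selection <- seq_len(nrow(a))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- unname(radii) + probe
  pts <- sphere_points(n_points)
  area <- numeric(length(selection))
  for (k in seq_along(selection)) {
    i <- selection[k]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R + R[i])^2 & seq_len(nrow(xyz)) != i)
    sp <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj <- rowSums(sweep(sp[accessible, , drop = FALSE], 2, xyz[j, ])^2)
      accessible[accessible][dj < R[j]^2] <- FALSE
    }
    area[k] <- 4 * pi * R[i]^2 * sum(accessible) / n_points
  }
  structure(list(area = stats::setNames(area, a$id[selection]),
                 total = sum(area), probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.1f A^2 (probe %.2f A)\n",
              length(x$area), x$total, x$probe))
  invisible(x)
}

#' Relative accessible surface area of the ligand
#'
#' SASA of the ligand atoms within the complex divided by the SASA of the
#' ligand extracted alone in the same conformation — a pure burial measure
#' of the binding pose: 1 for a fully solvent-exposed ligand, approaching 0
#' for complete burial.
#'
#' @param model a complex [structure_model()] containing receptor and
#'   ligand chains.
#' @param chain ligand chain id (default: all chains with role `"ligand"`).
#' @param probe,n_points passed to [sasa()].
#' @return Fraction in `[0, 1]`.
#' @export
rasa <- function(model, chain = NULL, probe = 1.4, n_points = 960) {
  if (is.null(chain)) {
    chain <- names(model$chain_roles)[model$chain_roles == "ligand"]
  }
  if (length(chain) == 0) stop("complex has no ligand chain")
  lig_idx <- which(model$atoms$chain %in% chain)
  in_complex <- sasa(model, lig_idx, probe, n_points)$total
  alone <- structure_model(model$atoms[lig_idx, ],
                           model$chain_roles[chain])
  isolated <- sasa(alone, probe = probe, n_points = n_points)$total
  in_complex / isolated
}

#' Pocket-gate distances
#'
#' C-alpha to C-alpha distances between named residue pairs along a binding
#' pocket (e.g. the five pairs `d0`-`d4` spanning a cryptic groove).
#'
#' @param model a [structure_model()].
#' @param pairs data frame (or 2-column matrix) of residue index pairs;
#'   optional `chain` column (defaults to the first receptor chain).
#' @return Named numeric vector `d0`, `d1`, ... of distances in Angstrom.
#' @export
pocket_distances <- function(model, pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("res_i", "res_j")
  if (!"chain" %in% names(pairs)) {
    rec <- names(model$chain_roles)[model$chain_roles == "receptor"]
    pairs$chain <- if (length(rec)) rec[1] else names(model$chain_roles)[1]
  }
  ca <- function(ch, res) {
    idx <- select_atoms(model, chain = ch, name = "CA", resid = res)
    if (length(idx) == 0) {
      stop("cannot resolve CA of residue ", res, " in chain ", ch)
    }
    as.numeric(model$atoms[idx[1], c("x", "y", "z")])
  }
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    sqrt(sum((ca(pairs$chain[k], pairs$res_i[k]) -
                ca(pairs$chain[k], pairs$res_j[k]))^2))
  }, numeric(1))
  stats::setNames(d, sprintf("d%d", seq_len(nrow(pairs)) - 1))
}

#' Dissociation coordinate of a structure
#'
#' Mass-weighted center of mass of the ligand atoms along the dissociation
#' axis in the receptor-fixed frame.
#'
#' @param model a [structure_model()].
#' @param chain ligand chain id(s) (default: chains with role `"ligand"`).
#' @param axis axis index (1 = x).
#' @return lambda in Angstrom.
#' @export
lambda_coord <- function(model, chain = NULL, axis = 1) {
  if (is.null(chain)) {
    chain <- names(model$chain_roles)[model$chain_roles == "ligand"]
  }
  sel <- which(model$atoms$chain %in% chain)
  if (length(sel) == 0) stop("no ligand atoms found")
  m <- element_mass(model$atoms$element[sel])
  v <- model$atoms[sel, c("x", "y", "z")][[axis]]
  sum(m * v) / sum(m)
}

#' Dissociation-coordinate series of an ensemble
#'
#' Vectorized [lambda_coord()] over every snapshot of an ensemble with a
#' [toy_system()] topology (bead masses from the system).
#'
#' @param ens an [ensemble()] with a toy-system topology.
#' @param axis axis index (1 = x).
#' @return Numeric vector, one lambda per snapshot.
#' @export
lambda_series <- function(ens, axis = 1) {
  sys <- ens$topology
  if (!inherits(sys, "toy_system")) stop("ensemble topology is not a toy_system")
  lig <- which(sys$chain_roles[sys$chains] == "ligand")
  m <- sys$masses[lig]
  cols <- 3 * (lig - 1) + axis
  as.numeric(ens$coords[, cols, drop = FALSE] %*% m / sum(m))
}
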