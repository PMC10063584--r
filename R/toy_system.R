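#' Coarse-grained toy system for desk-scale sampling
#'
#' A `toy_system` is a particle model with a small vocabulary of potential
#' terms, rich enough to express the ingredients of a cryptic-pocket binding
#' problem: harmonic springs (bonded connectivity and chain stiffness),
#' Gaussian pairwise site wells (attraction of ligand beads to binding
#' sub-sites, or soft steric repulsion from a gate bead), a double-well on a
#' single coordinate (the receptor gate), harmonic single-coordinate wells,
#' and the restraint forms used during dynamic docking (flat-bottom distance
#' restraints and a center-of-mass axis box).
#'
#' Term tables (all indices 1-based):
#' * `bonds`: columns `i, j, k, r0`; energy `k*(r - r0)^2`.
#' * `pairs`: columns `i, j, eps, sigma`; energy `eps*exp(-r^2/(2*sigma^2))`
#'   (negative `eps` = attraction).
#' * `dwells`: columns `i, axis, h, m, w, slope`; with `s = c - m` (where `c`
#'   is the particle's coordinate along `axis`), energy
#'   `h*((s^2 - w^2)/w^2)^2 + slope*s` — two minima near `m - w` and `m + w`,
#'   tilted by `slope`.
#' * `harm`: columns `i, axis, k, c0`; energy `k*(c - c0)^2`.
#'
#' @param coords0 reference configuration, `n x 3` matrix (Angstrom).
#' @param masses particle masses (amu); recycled if length one.
#' @param mobile `n x 3` 0/1 matrix marking which coordinates the sampler may
#'   move (fixed receptor scaffold beads have all-zero rows); recycled from a
#'   logical vector of length `n` if given as such.
#' @param chains character vector of chain ids per particle.
#' @param chain_roles named character vector, chain id -> role.
#' @param terms list of term matrices as described above (missing entries
#'   default to empty).
#' @param restraints list of [restraint_spec()] objects.
#' @param names optional particle names.
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(coords0, masses = 12, mobile = TRUE,
                       chains = "L", chain_roles = NULL,
                       terms = list(), restraints = list(), names = NULL) {
  coords0 <- as.matrix(coords0)
  if (ncol(coords0) != 3) stop("coords0 must be an n x 3 matrix")
  n <- nrow(coords0)
  masses <- rep_len(masses, n)
  if (is.vector(mobile)) mobile <- matrix(rep(as.numeric(mobile), 3), n, 3)
  mobile <- (as.matrix(mobile) != 0) * 1
  chains <- rep_len(chains, n)
  if (is.null(chain_roles)) {
    chain_roles <- stats::setNames(rep("ligand", length(unique(chains))),
                                   unique(chains))
  }
  if (is.null(names)) names <- sprintf("B%d", seq_len(n))
  defaults <- list(bonds = matrix(0, 0, 4), pairs = matrix(0, 0, 4),
                   dwells = matrix(0, 0, 6), harm = matrix(0, 0, 4))
  for (nm in names(defaults)) {
    if (is.null(terms[[nm]])) terms[[nm]] <- defaults[[nm]]
    terms[[nm]] <- matrix(as.numeric(terms[[nm]]), ncol = ncol(defaults[[nm]]))
    idx <- terms[[nm]][, if (nm %in% c("bonds", "pairs")) 1:2 else 1]
    if (length(idx) && (any(idx < 1) || any(idx > n))) {
      stop("term table '", nm, "' references a non-existent particle")
    }
  }
  sys <- structure(list(n = n, coords0 = coords0, masses = masses,
                        mobile = mobile, chains = chains,
                        chain_roles = chain_roles, terms = terms,
                        restraints = restraints, names = names),
                   class = "toy_system")
  e0 <- toy_energy(sys, coords0)
  if (!is.finite(e0)) stop("potential is not finite at the reference configuration")
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  nt <- vapply(x$terms, nrow, numeric(1))
  cat(sprintf("toy_system: %d particles (%d mobile coordinates), terms: %s, %d restraint(s)\n",
              x$n, sum(x$mobile),
              paste(sprintf("%s=%d", names(nt), nt), collapse = " "),
              length(x$restraints)))
  invisible(x)
}

#' Restraint specification
#'
#' Two restraint kinds are supported, both flat-bottomed with a quadratic
#' penalty `k * delta^2` beyond the flat region (`delta` = excess distance in
#' Angstrom):
#' * `"flat_bottom_distance"`: the distance between atoms `i` and `j` is free
#'   inside `[lo, hi]`.
#' * `"com_axis_box"`: the mass-weighted center of mass of the `group`
#'   particles, along `axis` (1 = x, 2 = y, 3 = z), is free inside
#'   `[lo, hi]`; motion perpendicular to the axis is never penalized.
#'
#' @param kind `"flat_bottom_distance"` or `"com_axis_box"`.
#' @param i,j atom indices (flat-bottom distance).
#' @param group integer vector of particle indices (COM box).
#' @param lo,hi flat-region bounds in Angstrom.
#' @param k force constant in kcal/mol/A^2 (>= 0).
#' @param axis axis index for `com_axis_box`.
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(kind = c("flat_bottom_distance", "com_axis_box"),
                           i = NULL, j = NULL, group = NULL,
                           lo, hi, k, axis = 1) {
  kind <- match.arg(kind)
  if (lo > hi) stop("flat-region lower bound exceeds upper bound")
  if (k < 0) stop("force constant must be non-negative")
  if (kind == "flat_bottom_distance" && (is.null(i) || is.null(j))) {
    stop("flat_bottom_distance requires atom indices i and j")
  }
  if (kind == "com_axis_box" && (is.null(group) || length(group) == 0)) {
    stop("com_axis_box requires a non-empty particle group")
  }
  structure(list(kind = kind, i = i, j = j, group = group,
                 lo = lo, hi = hi, k = k, axis = axis),
            class = "restraint_spec")
}

# quadratic flat-bottom penalty on a scalar value
.fb_penalty <- function(v, lo, hi, k) {
  if (v < lo) k * (lo - v)^2 else if (v > hi) k * (v - hi)^2 else 0
}

#' Restraint energy of a configuration
#'
#' Zero inside the flat region, `k * delta^2` beyond it. For
#' `com_axis_box` the penalty applies only along the named axis.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param spec a [restraint_spec()].
#' @param masses particle masses (needed for `com_axis_box`).
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(coords, spec, masses = NULL) {
  coords <- as.matrix(coords)
  if (spec$kind == "flat_bottom_distance") {
    if (any(c(spec$i, spec$j) > nrow(coords))) stop("restraint selection out of range")
    r <- sqrt(sum((coords[spec$i, ] - coords[spec$j, ])^2))
    return(.fb_penalty(r, spec$lo, spec$hi, spec$k))
  }
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  g <- spec$group
  if (any(g > nrow(coords))) stop("restraint selection out of range")
  com <- sum(masses[g] * coords[g, spec$axis]) / sum(masses[g])
  .fb_penalty(com, spec$lo, spec$hi, spec$k)
}

#' Total potential energy of a toy system
#'
#' Sum of all term and restraint energies at the given configuration
#' (defaults to the reference configuration).
#'
#' @param sys a [toy_system()].
#' @param coords `n x 3` coordinate matrix.
#' @return Energy in kcal/mol.
#' @export
toy_energy <- function(sys, coords = sys$coords0) {
  coords <- as.matrix(coords)
  e <- 0
  b <- sys$terms$bonds
  if (nrow(b)) {
    d <- sqrt(rowSums((coords[b[, 1], , drop = FALSE] -
                         coords[b[, 2], , drop = FALSE])^2))
    e <- e + sum(b[, 3] * (d - b[, 4])^2)
  }
  p <- sys$terms$pairs
  if (nrow(p)) {
    d2 <- rowSums((coords[p[, 1], , drop = FALSE] -
                     coords[p[, 2], , drop = FALSE])^2)
    e <- e + sum(p[, 3] * exp(-d2 / (2 * p[, 4]^2)))
  }
  dw <- sys$terms$dwells
  if (nrow(dw)) {
    s <- coords[cbind(dw[, 1], dw[, 2])] - dw[, 4]
    e <- e + sum(dw[, 3] * ((s^2 - dw[, 5]^2) / dw[, 5]^2)^2 + dw[, 6] * s)
  }
  h <- sys$terms$harm
  if (nrow(h)) {
    cvals <- coords[cbind(h[, 1], h[, 2])]
    e <- e + sum(h[, 3] * (cvals - h[, 4])^2)
  }
  for (rs in sys$restraints) e <- e + restraint_energy(coords, rs, sys$masses)
  e
}

#' Analytic gradient of the toy potential
#'
#' Returns `dU/dx` as an `n x 3` matrix; forces are its negative. Matches
#' central finite differences of [toy_energy()] (tested property).
#'
#' @inheritParams toy_energy
#' @return `n x 3` gradient matrix in kcal/mol/A.
#' @export
toy_gradient <- function(sys, coords = sys$coords0) {
  coords <- as.matrix(coords)
  g <- matrix(0, nrow(coords), 3)
  b <- sys$terms$bonds
  for (t in seq_len(nrow(b))) {
    i <- b[t, 1]; j <- b[t, 2]
    dv <- coords[i, ] - coords[j, ]
    r <- sqrt(sum(dv^2))
    if (r > 0) {
      f <- 2 * b[t, 3] * (r - b[t, 4]) * dv / r
      g[i, ] <- g[i, ] + f; g[j, ] <- g[j, ] - f
    }
  }
  p <- sys$terms$pairs
  for (t in seq_len(nrow(p))) {
    i <- p[t, 1]; j <- p[t, 2]
    dv <- coords[i, ] - coords[j, ]
    f <- -p[t, 3] * exp(-sum(dv^2) / (2 * p[t, 4]^2)) * dv / p[t, 4]^2
    g[i, ] <- g[i, ] + f; g[j, ] <- g[j, ] - f
  }
  dw <- sys$terms$dwells
  for (t in seq_len(nrow(dw))) {
    i <- dw[t, 1]; ax <- dw[t, 2]
    s <- coords[i, ax] - dw[t, 4]
    g[i, ax] <- g[i, ax] + dw[t, 3] * 4 * s * (s^2 - dw[t, 5]^2) / dw[t, 5]^4 +
      dw[t, 6]
  }
  h <- sys$terms$harm
  for (t in seq_len(nrow(h))) {
    i <- h[t, 1]; ax <- h[t, 2]
    g[i, ax] <- g[i, ax] + 2 * h[t, 3] * (coords[i, ax] - h[t, 4])
  }
  for (rs in sys$restraints) {
    if (rs$kind == "flat_bottom_distance") {
      dv <- coords[rs$i, ] - coords[rs$j, ]
      r <- sqrt(sum(dv^2))
      excess <- if (r > rs$hi) r - rs$hi else if (r < rs$lo) r - rs$lo else 0
      if (excess != 0 && r > 0) {
        f <- 2 * rs$k * excess * dv / r
        g[rs$i, ] <- g[rs$i, ] + f; g[rs$j, ] <- g[rs$j, ] - f
      }
    } else {
      m <- sys$masses[rs$group]; M <- sum(m)
      com <- sum(m * coords[rs$group, rs$axis]) / M
      excess <- if (com > rs$hi) com - rs$hi else if (com < rs$lo) com - rs$lo else 0
      if (excess != 0) {
        g[rs$group, rs$axis] <- g[rs$group, rs$axis] + 2 * rs$k * excess * m / M
      }
    }
  }
  g
}

#' Render a toy-system configuration as a structure model
#'
#' Each bead becomes a carbon pseudo-atom named `CA` in its own residue, so
#' that contact, R-value, RMSD and distance machinery applies unchanged to
#' toy ensembles.
#'
#' @param sys a [toy_system()].
#' @param coords `n x 3` coordinate matrix (defaults to the reference).
#' @return A [structure_model()].
#' @export
toy_structure <- function(sys, coords = sys$coords0) {
  coords <- as.matrix(coords)
  resid <- stats::ave(seq_len(sys$n), sys$chains, FUN = seq_along)
  atoms <- data.frame(id = seq_len(sys$n), name = "CA", element = "C",
                      resname = "BEA", resid = as.integer(resid),
                      chain = sys$chains,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  ord <- order(match(atoms$chain, unique(sys$chains)), atoms$resid)
  structure_model(atoms[ord, ], sys$chain_roles)
}
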