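#' Windows along the dissociation coordinate
#'
#' Splits `[lambda_min, lambda_max]` into contiguous, non-overlapping
#' windows of the given width; the last window is truncated at
#' `lambda_max`. The conventional restrained range is -2.5 to 40.0 Angstrom,
#' which a 2.5 Angstrom width splits into 17 windows.
#'
#' @param lambda_min,lambda_max range bounds in Angstrom.
#' @param width window width in Angstrom (> 0).
#' @return An object of class `window_spec`: data frame with `window`,
#'   `lo`, `hi`.
#' @export
make_windows <- function(lambda_min, lambda_max, width = 2.5) {
  if (width <= 0) stop("window width must be positive")
  if (lambda_max <= lambda_min) stop("lambda_max must exceed lambda_min")
  n <- ceiling((lambda_max - lambda_min) / width - 1e-9)
  lo <- lambda_min + (seq_len(n) - 1) * width
  hi <- pmin(lo + width, lambda_max)
  structure(data.frame(window = seq_len(n), lo = lo, hi = hi),
            class = c("window_spec", "data.frame"))
}

#' Extract a connected binding pathway along the dissociation coordinate
#'
#' Starting from a bound snapshot in the first window, each subsequent
#' window's pick is the snapshot (among those whose lambda falls inside the
#' window) that maximizes the R-value against the previous pick; ties are
#' broken by lower ligand RMSD to the previous pick, then by lower snapshot
#' index. This traces a smoothly connected dissociation path through the
#' multicanonical ensemble without any free-energy pre-filtering.
#'
#' @param ens an [ensemble()] with a topology.
#' @param lambda per-snapshot dissociation coordinate (Angstrom), e.g. from
#'   [lambda_coord()].
#' @param start snapshot index of the bound starting structure; its lambda
#'   must lie in the first window.
#' @param windows a [make_windows()] spec.
#' @param scope,cutoff contact definition for the R-value.
#' @return An object of class `pathway`: data frame with `window`, `lo`,
#'   `hi`, `snapshot`, `lambda`, `r_prev`, `rmsd_prev` (similarity of each
#'   pick to the previous one; NA for the start).
#' @export
extract_pathway <- function(ens, lambda, start, windows,
                            scope = "inter", cutoff = 4.5) {
  if (length(lambda) != n_snapshots(ens)) {
    stop("lambda must have one value per snapshot")
  }
  w1 <- windows[1, ]
  if (lambda[start] < w1$lo || lambda[start] > w1$hi) {
    stop(sprintf("start snapshot lambda %.2f outside the first window [%.2f, %.2f]",
                 lambda[start], w1$lo, w1$hi))
  }
  picks <- integer(nrow(windows))
  r_prev <- rmsd_prev <- rep(NA_real_, nrow(windows))
  picks[1] <- start
  # all-snapshot contact flags, computed once (same pair keys and cutoff as
  # contact_set, vectorized over frames)
  C <- .contact_flags(ens, scope, cutoff)
  prev <- start
  for (k in seq_len(nrow(windows))[-1]) {
    members <- which(lambda >= windows$lo[k] & lambda < windows$hi[k])
    if (k == nrow(windows)) {
      members <- which(lambda >= windows$lo[k] & lambda <= windows$hi[k])
    }
    if (length(members) == 0) {
      stop(sprintf("window %d [%.2f, %.2f] contains no snapshots; widen the windows",
                   k, windows$lo[k], windows$hi[k]))
    }
    ref <- C[prev, ]
    rv <- if (sum(ref) == 0) rep(0, length(members)) else
      as.numeric(C[members, ref, drop = FALSE] %*% rep(1, sum(ref))) / sum(ref)
    best_r <- max(rv)
    cand <- members[rv == best_r]
    if (length(cand) > 1) {
      rms <- .ligand_rmsd_rows(ens, cand, prev)
      cand <- cand[rms == min(rms)]
    }
    picks[k] <- min(cand)
    r_prev[k] <- best_r
    rmsd_prev[k] <- .ligand_rmsd_rows(ens, picks[k], prev)
    prev <- picks[k]
  }
  structure(data.frame(window = windows$window, lo = windows$lo,
                       hi = windows$hi, snapshot = picks,
                       lambda = lambda[picks], r_prev = r_prev,
                       rmsd_prev = rmsd_prev),
            ens = ens, scope = scope, cutoff = cutoff,
            class = c("pathway", "data.frame"))
}

# Ligand heavy-atom RMSD of snapshots `rows` against snapshot `ref`, in the
# receptor frame. For toy systems with an immobile receptor scaffold the
# receptor frame equals the lab frame and the computation is vectorized over
# rows; otherwise it falls back to per-snapshot superposition.
.ligand_rmsd_rows <- function(ens, rows, ref) {
  topo <- ens$topology
  if (inherits(topo, "toy_system")) {
    rec <- which(topo$chain_roles[topo$chains] == "receptor")
    # an immobile receptor scaffold pins the receptor frame to the lab frame
    anchored <- length(rec) > 0 && any(rowSums(topo$mobile[rec, , drop = FALSE]) == 0)
    if (anchored) {
      lig <- which(topo$chain_roles[topo$chains] == "ligand")
      cols <- as.vector(t(outer(3 * (lig - 1), 1:3, `+`)))
      dev <- sweep(ens$coords[rows, cols, drop = FALSE], 2,
                   ens$coords[ref, cols])
      return(sqrt(rowSums(dev^2) / length(lig)))
    }
  }
  ref_struct <- snapshot_structure(ens, ref)
  vapply(rows, function(s)
    ligand_rmsd(snapshot_structure(ens, s), ref_struct), numeric(1))
}

# Per-snapshot contact flags for every in-scope heavy-atom pair, vectorized
# over frames. Row s column "i-j" equals membership of pair (i, j) in
# contact_set(snapshot_structure(ens, s), scope, cutoff).
.contact_flags <- function(ens, scope = "inter", cutoff = 4.5) {
  st <- snapshot_structure(ens, 1)
  a <- st$atoms
  heavy <- which(toupper(a$element) != "H")
  cmb <- utils::combn(heavy, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  roles <- st$chain_roles
  inter <- roles[a$chain[i]] != roles[a$chain[j]]
  intra <- a$chain[i] == a$chain[j] & abs(a$resid[i] - a$resid[j]) > 2
  keep <- switch(scope, inter = inter, intra = intra, both = inter | intra)
  i <- i[keep]; j <- j[keep]
  if (length(i) * n_snapshots(ens) > 5e8) {
    stop("contact matrix too large; restrict the scope or subsample")
  }
  # map structure rows back to coordinate columns: toy_structure keeps the
  # particle index in the id column; plain models use row order
  pidx <- if (inherits(ens$topology, "toy_system")) a$id else seq_len(nrow(a))
  d2 <- 0
  for (ax in 1:3) {
    dx <- ens$coords[, 3 * (pidx[i] - 1) + ax, drop = FALSE] -
      ens$coords[, 3 * (pidx[j] - 1) + ax, drop = FALSE]
    d2 <- d2 + dx^2
  }
  M <- d2 <= cutoff^2
  colnames(M) <- sprintf("%d-%d", i, j)
  M
}

#' Neighbor-similarity table of a pathway
#'
#' Per consecutive pair of picks: the R-value of the later pick with the
#' earlier one as reference, and the ligand RMSD in the receptor frame.
#' Steps with R below `flag_threshold` (default 0.6) are marked as putative
#' barrier crossings — low contact preservation between neighboring windows
#' suggests a high energy barrier in that region.
#'
#' @param path an [extract_pathway()] result.
#' @param flag_threshold barrier flag threshold on R.
#' @return Data frame with `window`, `r`, `rmsd`, `barrier`.
#' @export
window_similarity <- function(path, flag_threshold = 0.6) {
  if (nrow(path) < 2) stop("pathway needs at least two picks")
  out <- data.frame(window = path$window[-1], r = path$r_prev[-1],
                    rmsd = path$rmsd_prev[-1])
  out$barrier <- out$r < flag_threshold
  out
}

#' Export pathway picks as a multi-model PDB
#'
#' @param path an [extract_pathway()] result.
#' @param file output path.
#' @export
write_pathway_pdb <- function(path, file) {
  ens <- attr(path, "ens")
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(path))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(write_structure(snapshot_structure(ens, path$snapshot[k])), con)
    writeLines("ENDMDL", con)
  }
  invisible(file)
}
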