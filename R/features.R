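#' Select atom indices from a structure model
#'
#' Small helper used to assemble selection specs: filters by chain role,
#' chain id, atom name and residue index, returning row indices into
#' `model$atoms`.
#'
#' @param model a [structure_model()].
#' @param role optional chain role (`"receptor"` / `"ligand"`).
#' @param chain optional chain id(s).
#' @param name optional atom name(s).
#' @param resid optional residue indices.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(model, role = NULL, chain = NULL, name = NULL,
                         resid = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) {
    keep <- keep & a$chain %in% names(model$chain_roles)[model$chain_roles == role]
  }
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  which(keep)
}

#' Atom-pair selection for distance features
#'
#' Assembles the named atom-pair groups of the distance array used for the
#' landscape PCA:
#' * intermolecular pairs — every receptor anchor against every ligand atom;
#' * ligand intramolecular pairs — all pairs among `ligand_atoms` whose
#'   residues are further apart than the sequence-exclusion window
#'   (`|i - j| > exclusion`, applied only within one chain);
#' * receptor flexibility pairs — an explicit two-column index matrix (e.g.
#'   pocket-helix atoms against a buried core anchor).
#'
#' @param model the topology ([structure_model()]) the indices refer to.
#' @param receptor_anchors atom indices on the receptor.
#' @param ligand_atoms atom indices on the ligand.
#' @param exclusion sequence-exclusion window `m` of `i +/- m` (default 3).
#' @param receptor_pairs optional 2-column matrix of extra receptor pairs.
#' @param intermolecular,ligand_intra logical switches for the two generated
#'   groups.
#' @return An object of class `selection_spec` with a `pairs` matrix and
#'   per-pair `group` labels.
#' @export
selection_spec <- function(model, receptor_anchors = NULL, ligand_atoms = NULL,
                           exclusion = 3, receptor_pairs = NULL,
                           intermolecular = TRUE, ligand_intra = TRUE) {
  a <- model$atoms
  pairs <- matrix(integer(0), 0, 2)
  group <- character(0)
  if (intermolecular && length(receptor_anchors) && length(ligand_atoms)) {
    g <- expand.grid(i = receptor_anchors, j = ligand_atoms)
    pairs <- rbind(pairs, as.matrix(g))
    group <- c(group, rep("inter", nrow(g)))
  }
  if (ligand_intra && length(ligand_atoms) > 1) {
    cmb <- utils::combn(sort(ligand_atoms), 2)
    same_chain <- a$chain[cmb[1, ]] == a$chain[cmb[2, ]]
    dres <- abs(a$resid[cmb[1, ]] - a$resid[cmb[2, ]])
    keep <- !same_chain | dres > exclusion
    keep <- keep & !(cmb[1, ] == cmb[2, ])
    if (any(keep)) {
      pairs <- rbind(pairs, t(cmb[, keep, drop = FALSE]))
      group <- c(group, rep("ligand_intra", sum(keep)))
    }
  }
  if (!is.null(receptor_pairs)) {
    receptor_pairs <- matrix(as.integer(receptor_pairs), ncol = 2)
    pairs <- rbind(pairs, receptor_pairs)
    group <- c(group, rep("receptor_flex", nrow(receptor_pairs)))
  }
  if (nrow(pairs) == 0) stop("selection produced no atom pairs")
  if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
  bad <- unique(c(pairs))[!unique(c(pairs)) %in% seq_len(nrow(a))]
  if (length(bad)) {
    stop("selection references missing atoms: ", paste(bad, collapse = ", "))
  }
  labels <- sprintf("%s:%s%d.%s-%s%d.%s", group,
                    a$chain[pairs[, 1]], a$resid[pairs[, 1]], a$name[pairs[, 1]],
                    a$chain[pairs[, 2]], a$resid[pairs[, 2]], a$name[pairs[, 2]])
  structure(list(pairs = pairs, group = group, labels = labels,
                 exclusion = exclusion), class = "selection_spec")
}

#' Distance-array features of an ensemble
#'
#' Euclidean distances, one column per selected atom pair, one row per
#' snapshot, in the spec's pair order. Distances are superposition-free
#' (invariant under global rotation/translation of each frame). When the
#' ensemble metadata declares a periodic `box` (length-3 vector), the
#' minimum-image convention is applied per axis.
#'
#' @param ens an [ensemble()] whose coordinate layout matches the model used
#'   to build `spec`.
#' @param spec a [selection_spec()].
#' @return A numeric matrix (`feature_matrix`), columns labelled by pair.
#' @export
build_distance_features <- function(ens, spec) {
  X <- ens$coords
  n_atoms <- ncol(X) / 3
  if (any(spec$pairs > n_atoms)) {
    stop("selection references missing atoms: ",
         paste(unique(spec$pairs[spec$pairs > n_atoms]), collapse = ", "))
  }
  box <- ens$metadata$box
  i <- spec$pairs[, 1]; j <- spec$pairs[, 2]
  d2 <- 0
  for (ax in 1:3) {
    dx <- X[, 3 * (i - 1) + ax, drop = FALSE] - X[, 3 * (j - 1) + ax, drop = FALSE]
    if (!is.null(box)) dx <- dx - box[ax] * round(dx / box[ax])
    d2 <- d2 + dx^2
  }
  D <- sqrt(d2)
  colnames(D) <- spec$labels
  class(D) <- c("feature_matrix", class(D))
  D
}

#' Principal component analysis of a feature matrix
#'
#' Eigendecomposition of the (optionally weighted) covariance of the centered
#' columns. Per-component variance contributions are reported in percent and
#' are non-increasing. The eigenvector sign convention is fixed — the
#' largest-magnitude loading of each component is made positive — so scores
#' are reproducible bit-for-bit given a fixed snapshot order.
#'
#' @param features numeric matrix, snapshots in rows.
#' @param weights optional `weight_vector` (or numeric) snapshot weights for
#'   the covariance; by default the raw (unweighted) ensemble is analyzed
#'   and reweighting enters only at the landscape-probability step.
#' @return An object of class `projection`: `rotation` (loadings),
#'   `contrib` (percent variance per component), `scores`, `center`.
#' @export
pca_fit_project <- function(features, weights = NULL) {
  X <- unclass(as.matrix(features))
  if (nrow(X) < 2) stop("need at least 2 snapshots for PCA")
  w <- if (is.null(weights)) rep(1 / nrow(X), nrow(X)) else
    (if (inherits(weights, "weight_vector")) weights$w else weights / sum(weights))
  ctr <- colSums(X * w)
  Xc <- sweep(X, 2, ctr)
  C <- crossprod(Xc * sqrt(w))
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  if (sum(vals) <= 0) stop("feature matrix has zero variance (rank 0)")
  V <- ev$vectors
  for (k in seq_len(ncol(V))) {            # deterministic sign convention
    m <- which.max(abs(V[, k]))
    if (V[m, k] < 0) V[, k] <- -V[, k]
  }
  scores <- Xc %*% V
  colnames(scores) <- colnames(V) <- sprintf("PC%d", seq_len(ncol(V)))
  structure(list(rotation = V, contrib = 100 * vals / sum(vals),
                 scores = scores, center = ctr),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("projection: %d snapshots x %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), x$contrib[1],
              if (length(x$contrib) > 1) x$contrib[2] else 0))
  invisible(x)
}

#' Number of components needed to reach a cumulative variance threshold
#'
#' @param projection a [pca_fit_project()] result.
#' @param threshold cumulative percent-variance threshold (default 90).
#' @return Smallest component count whose cumulative contribution exceeds
#'   the threshold.
#' @export
n_components <- function(projection, threshold = 90) {
  m <- which(cumsum(projection$contrib) > threshold)[1]
  if (is.na(m)) length(projection$contrib) else m
}

#' Reweighted 2-D free-energy landscape
#'
#' Bins the first two score columns on a regular grid, sums the snapshot
#' weights per bin (`P_i`), and converts to a potential of mean force
#' `PMF_i = -R*T*ln(P_i)`, shifted so its minimum is zero. Empty bins and
#' bins above the display cutoff (default 5 kcal/mol) are flagged.
#'
#' @param projection a `projection` (or plain score matrix; first two
#'   columns are used).
#' @param weights a `weight_vector` of normalized snapshot weights.
#' @param T temperature in K.
#' @param nbins bins per axis (default 100 x 100).
#' @param cutoff display cutoff in kcal/mol.
#' @param edges optional list with `x` and `y` bin edges overriding the
#'   default range (score range padded by 2%); an error names suggested
#'   bounds if scores fall outside the supplied grid.
#' @return An object of class `fel_grid` with `xedges`, `yedges`, `P`,
#'   `pmf`, `flagged`, `T`, `cutoff`.
#' @export
compute_fel <- function(projection, weights, T = 300, nbins = 100,
                        cutoff = 5, edges = NULL) {
  S <- if (inherits(projection, "projection")) projection$scores else as.matrix(projection)
  x <- S[, 1]; y <- S[, 2]
  w <- if (inherits(weights, "weight_vector")) weights$w else weights
  if (abs(sum(w) - 1) > 1e-6) stop("weights must be normalized")
  if (is.null(edges)) {
    pad <- function(r) r + c(-1, 1) * 0.02 * max(diff(r), .Machine$double.eps)
    rx <- pad(range(x)); ry <- pad(range(y))
    edges <- list(x = seq(rx[1], rx[2], length.out = nbins + 1),
                  y = seq(ry[1], ry[2], length.out = nbins + 1))
  }
  if (min(x) < edges$x[1] || max(x) > edges$x[length(edges$x)] ||
      min(y) < edges$y[1] || max(y) > edges$y[length(edges$y)]) {
    stop(sprintf("grid does not cover the scores; suggested bounds x: [%.3g, %.3g], y: [%.3g, %.3g]",
                 min(x), max(x), min(y), max(y)))
  }
  bx <- pmin(findInterval(x, edges$x, rightmost.closed = TRUE),
             length(edges$x) - 1)
  by <- pmin(findInterval(y, edges$y, rightmost.closed = TRUE),
             length(edges$y) - 1)
  P <- matrix(0, length(edges$x) - 1, length(edges$y) - 1)
  for (k in seq_along(x)) P[bx[k], by[k]] <- P[bx[k], by[k]] + w[k]
  pmf <- matrix(Inf, nrow(P), ncol(P))
  pos <- P > 0
  pmf[pos] <- -GAS_CONSTANT * T * log(P[pos])
  pmf <- pmf - min(pmf[pos])
  structure(list(xedges = edges$x, yedges = edges$y, P = P, pmf = pmf,
                 flagged = !pos | pmf > cutoff, T = T, cutoff = cutoff),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("fel_grid: %d x %d bins at %g K, %d occupied, cutoff %g kcal/mol\n",
              nrow(x$pmf), ncol(x$pmf), x$T, sum(x$P > 0), x$cutoff))
  invisible(x)
}

#' Landscape free energy at a point
#'
#' PMF of the bin containing `(x, y)`; `Inf` for empty bins.
#'
#' @param fel a [compute_fel()] result.
#' @param x,y coordinates on the landscape.
#' @export
fel_value <- function(fel, x, y) {
  bx <- pmin(findInterval(x, fel$xedges, rightmost.closed = TRUE),
             length(fel$xedges) - 1)
  by <- pmin(findInterval(y, fel$yedges, rightmost.closed = TRUE),
             length(fel$yedges) - 1)
  if (any(bx < 1 | by < 1)) stop("point outside the landscape grid")
  fel$pmf[cbind(bx, by)]
}

#' Export a landscape as a delimited table
#'
#' One row per bin with bin centers, probability, PMF and the cutoff flag.
#'
#' @param fel a [compute_fel()] result.
#' @param file output path.
#' @export
write_fel <- function(fel, file) {
  xm <- (fel$xedges[-1] + fel$xedges[-length(fel$xedges)]) / 2
  ym <- (fel$yedges[-1] + fel$yedges[-length(fel$yedges)]) / 2
  g <- expand.grid(x = seq_along(xm), y = seq_along(ym))
  tab <- data.frame(pc1 = xm[g$x], pc2 = ym[g$y],
                    P = fel$P[cbind(g$x, g$y)],
                    pmf = fel$pmf[cbind(g$x, g$y)],
                    flagged = fel$flagged[cbind(g$x, g$y)])
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
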