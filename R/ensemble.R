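#' Ensemble of sampled snapshots
#'
#' An `ensemble` stores the output of a sampling run: one coordinate row per
#' saved frame (flattened `x1 y1 z1 x2 y2 z2 ...` in Angstrom), the potential
#' energy of each frame in kcal/mol, and sampling metadata (the sampling
#' temperature `T_mc`, a bias identifier, the save interval and per-frame
#' trajectory/frame bookkeeping). All frames share one topology.
#'
#' @param coords numeric matrix, `n_frames x n_coords`.
#' @param energy numeric vector of per-frame potential energies.
#' @param topology optional topology object (a [toy_system()] or
#'   [structure_model()]) shared by every frame.
#' @param metadata list of sampling metadata; `T_mc`, `bias_id` and
#'   `save_interval` are conventional entries.
#' @param traj,frame optional per-snapshot trajectory id and frame index.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(coords, energy, topology = NULL, metadata = list(),
                     traj = NULL, frame = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("ensemble must contain at least one snapshot")
  if (length(energy) != nrow(coords)) {
    stop("energy length does not match snapshot count")
  }
  if (!all(is.finite(energy))) stop("non-finite snapshot energies")
  if (is.null(traj)) traj <- rep(1L, nrow(coords))
  if (is.null(frame)) frame <- seq_len(nrow(coords))
  structure(list(coords = coords, energy = as.numeric(energy),
                 topology = topology, metadata = metadata,
                 traj = as.integer(traj), frame = as.integer(frame)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d snapshots, %d coordinates each\n",
              nrow(x$coords), ncol(x$coords)))
  if (!is.null(x$metadata$T_mc)) {
    cat(sprintf("  sampled at T_mc = %g K (bias: %s)\n", x$metadata$T_mc,
                x$metadata$bias_id %||% "none"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of snapshots in an ensemble
#' @param x an [ensemble()].
#' @export
n_snapshots <- function(x) nrow(x$coords)

#' Subset an ensemble by snapshot index
#' @param x an [ensemble()].
#' @param i integer or logical snapshot index.
#' @param ... unused.
#' @export
`[.ensemble` <- function(x, i, ...) {
  ensemble(x$coords[i, , drop = FALSE], x$energy[i], x$topology, x$metadata,
           x$traj[i], x$frame[i])
}

#' Concatenate ensembles sharing a topology
#' @param ... ensembles with identical coordinate dimensionality.
#' @export
bind_ensembles <- function(...) {
  es <- list(...)
  if (length(es) == 1 && is.list(es[[1]]) && !inherits(es[[1]], "ensemble")) {
    es <- es[[1]]
  }
  nc <- vapply(es, function(e) ncol(e$coords), numeric(1))
  if (length(unique(nc)) != 1) stop("ensembles have differing topologies")
  ensemble(do.call(rbind, lapply(es, function(e) e$coords)),
           unlist(lapply(es, function(e) e$energy)),
           es[[1]]$topology, es[[1]]$metadata,
           unlist(lapply(seq_along(es), function(k) {
             es[[k]]$traj + if (k > 1) max(unlist(lapply(es[1:(k - 1)],
                                                         function(e) e$traj))) else 0L
           })),
           unlist(lapply(es, function(e) e$frame)))
}

#' Plain-text exchange form for ensembles
#'
#' Writes (or reads) an ensemble as a self-describing tab-separated text
#' file: a `#` header with the metadata, then one row per frame with the
#' trajectory id, frame index, energy and flattened coordinates. Intended for
#' small fixtures and cross-tool exchange; large runs should stay in memory.
#'
#' @param x an [ensemble()].
#' @param file path to write to / read from.
#' @return `read_ensemble_text()` returns an [ensemble()] (without topology).
#' @export
write_ensemble_text <- function(x, file) {
  hdr <- sprintf("# mcdock-ensemble n=%d ncoord=%d T_mc=%s bias_id=%s save_interval=%s",
                 nrow(x$coords), ncol(x$coords),
                 x$metadata$T_mc %||% "NA", x$metadata$bias_id %||% "NA",
                 x$metadata$save_interval %||% "NA")
  tab <- cbind(x$traj, x$frame, x$energy, x$coords)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 10, trim = TRUE), con,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_ensemble_text
#' @export
read_ensemble_text <- function(file) {
  hdr <- readLines(file, n = 1)
  if (!startsWith(hdr, "# mcdock-ensemble")) {
    stop("not an mcdock ensemble text file: ", file)
  }
  kv <- strsplit(strsplit(sub("^# mcdock-ensemble ", "", hdr), " ")[[1]], "=")
  meta <- stats::setNames(lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2])); if (is.na(v)) NULL else v
  }), vapply(kv, `[[`, "", 1))
  tab <- as.matrix(utils::read.table(file, skip = 1, sep = "\t"))
  ensemble(tab[, -(1:3), drop = FALSE], tab[, 3],
           metadata = meta[!vapply(meta, is.null, TRUE)],
           traj = tab[, 1], frame = tab[, 2])
}

#' Extract one snapshot as a structure model
#'
#' Reconstitutes frame `i` of an ensemble whose topology is a
#' [toy_system()] or [structure_model()], substituting the frame coordinates.
#'
#' @param ens an [ensemble()] with a topology.
#' @param i snapshot index.
#' @return A [structure_model()].
#' @export
snapshot_structure <- function(ens, i) {
  topo <- ens$topology
  if (is.null(topo)) stop("ensemble has no topology")
  xyz <- matrix(ens$coords[i, ], ncol = 3, byrow = TRUE)
  if (inherits(topo, "toy_system")) return(toy_structure(topo, xyz))
  if (inherits(topo, "structure_model")) {
    m <- topo
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    return(m)
  }
  stop("unsupported topology class")
}
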