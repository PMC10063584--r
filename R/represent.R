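# k-means++ seeding: D^2-weighted center choice with its own RNG stream so
# clustering is deterministic given the seed and independent of global state.
kmeanspp_centers <- function(X, k, rng) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- floor(rng$unif() * n) + 1
  centers[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) {
    for (c in 2:k) {
      if (sum(d2) <= 0) {
        pick <- floor(rng$unif() * n) + 1
      } else {
        u <- rng$unif() * sum(d2)
        pick <- findInterval(u, cumsum(d2)) + 1
        pick <- min(max(pick, 1), n)
      }
      centers[c, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[c, ])^2))
    }
  }
  centers
}

# tiny deterministic uniform stream (xorshift-like) for seeding
make_rng <- function(seed) {
  state <- as.double((abs(seed) %% 2147483647) + 1)
  list(unif = function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483648
  })
}

#' K-means clustering of projected snapshots
#'
#' Clusters the first `dims` principal-component score columns into
#' `k_prime` clusters using k-means++ seeding followed by Lloyd iteration
#' (`stats::kmeans`), with `n_restarts` independent seedings; the restart
#' with the lowest total within-cluster sum of squares is kept. Deterministic
#' given `seed`. The conventional production setting is `k_prime = 1000`
#' with `dims` chosen so the cumulative variance contribution exceeds 90%;
#' for desk-scale ensembles use [default_k_prime()].
#'
#' @param projection a [pca_fit_project()] result.
#' @param k_prime number of clusters (must not exceed the snapshot count).
#' @param dims number of leading score columns to cluster on; default from
#'   the 90% cumulative-variance rule.
#' @param seed integer seed.
#' @param n_restarts k-means++ restarts.
#' @return An object of class `cluster_set`: `labels`, `centroids`,
#'   `k_prime`, `dims`, `inertia`, `seed`.
#' @export
cluster_pc <- function(projection, k_prime, dims = n_components(projection),
                       seed = 1, n_restarts = 10) {
  S <- projection$scores[, seq_len(dims), drop = FALSE]
  n <- nrow(S)
  if (k_prime > n) stop("k_prime exceeds the number of snapshots")
  if (k_prime == n) {
    return(structure(list(labels = seq_len(n), centroids = S,
                          k_prime = k_prime, dims = dims, inertia = 0,
                          seed = seed), class = "cluster_set"))
  }
  rng <- make_rng(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_centers(S, k_prime, rng)
    km <- suppressWarnings(stats::kmeans(S, centers = init,
                                         iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(labels = best$cluster, centroids = best$centers,
                 k_prime = k_prime, dims = dims,
                 inertia = best$tot.withinss, seed = seed),
            class = "cluster_set")
}

#' Desk-scale default cluster count
#'
#' The production choice `k' = 1000` presumes millions of snapshots; for a
#' small ensemble of `n` snapshots the default is `min(1000, floor(n/10))`.
#'
#' @param n snapshot count.
#' @export
default_k_prime <- function(n) max(1L, min(1000L, n %/% 10L))

#' Cluster free energies
#'
#' Each cluster's reweighted probability mass is the sum of its members'
#' canonical weights; the cluster free energy is `CFE = -R*T*ln(P)`, shifted
#' so the most populated cluster sits at zero, and the table is ranked by
#' ascending CFE. Empty clusters are flagged and excluded.
#'
#' @param clusters a [cluster_pc()] result.
#' @param weights a `weight_vector` normalized over the clustered snapshots.
#' @param T temperature in K.
#' @return Data frame (class `cfe_table`) with `cluster`, `P`, `cfe`,
#'   `rank`, sorted by rank.
#' @export
cluster_free_energy <- function(clusters, weights, T = 300) {
  w <- if (inherits(weights, "weight_vector")) weights$w else weights
  P <- vapply(seq_len(clusters$k_prime),
              function(k) sum(w[clusters$labels == k]), numeric(1))
  empty <- P <= 0
  if (any(empty)) {
    warning(sum(empty), " empty cluster(s) excluded (CFE undefined)")
  }
  cfe <- rep(NA_real_, length(P))
  cfe[!empty] <- -GAS_CONSTANT * T * log(P[!empty])
  cfe <- cfe - min(cfe, na.rm = TRUE)
  tab <- data.frame(cluster = seq_along(P), P = P, cfe = cfe)
  tab <- tab[!empty, ]
  tab <- tab[order(tab$cfe, tab$cluster), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, T = T, class = c("cfe_table", "data.frame"))
}

#' Pick one representative snapshot per cluster
#'
#' The member with the minimum Euclidean distance to its cluster centroid in
#' the clustered PC subspace; ties are broken by the lowest snapshot index.
#'
#' @param clusters a [cluster_pc()] result.
#' @param projection the [pca_fit_project()] result the clusters were built
#'   on.
#' @return Integer vector: snapshot index per cluster (NA for empty ones).
#' @export
pick_representatives <- function(clusters, projection) {
  S <- projection$scores[, seq_len(clusters$dims), drop = FALSE]
  vapply(seq_len(clusters$k_prime), function(k) {
    members <- which(clusters$labels == k)
    if (length(members) == 0) return(NA_integer_)
    d2 <- rowSums(sweep(S[members, , drop = FALSE], 2,
                        clusters$centroids[k, ])^2)
    members[which.min(d2)]  # which.min returns the first (lowest index) tie
  }, integer(1))
}

#' Merge representatives by contact similarity
#'
#' Greedy pass over cluster representatives in ascending-CFE order: each
#' candidate is compared (R-value, intermolecular scope by default) against
#' every already-retained representative; on the first retained one scoring
#' above the threshold, the candidate's probability mass is added to it and
#' the candidate is dropped (the retained, more stable representative keeps
#' its snapshot). CFEs are recomputed from the merged masses and re-shifted
#' to a zero minimum. Representatives below `cfe_cutoff` form the stable
#' set.
#'
#' @param cfe a [cluster_free_energy()] table.
#' @param reps snapshot indices per cluster from [pick_representatives()].
#' @param ens the [ensemble()] the snapshots live in (topology required).
#' @param threshold R-value merge threshold in (0, 1]; default 0.7.
#' @param cfe_cutoff stable-set cutoff in kcal/mol; default 2.5.
#' @param T temperature for the CFE recomputation.
#' @param scope,cutoff contact definition passed to [r_value()].
#' @return An object of class `representative_set`: data frame with
#'   `rank`, `cluster`, `snapshot`, `P`, `cfe`, `stable`, `merged_from`
#'   (comma-separated lineage of merged cluster ids).
#' @export
merge_by_rvalue <- function(cfe, reps, ens, threshold = 0.7,
                            cfe_cutoff = 2.5, T = 300,
                            scope = "inter", cutoff = 4.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ord <- cfe[order(cfe$rank), ]
  # contact sets of every representative computed once up front
  csets <- lapply(seq_len(nrow(ord)), function(r) {
    snap <- reps[ord$cluster[r]]
    if (is.na(snap)) return(NULL)
    as.character(contact_set(snapshot_structure(ens, snap), scope, cutoff))
  })
  retained <- list()
  for (r in seq_len(nrow(ord))) {
    cl <- ord$cluster[r]
    snap <- reps[cl]
    if (is.na(snap)) next
    cand <- csets[[r]]
    merged <- FALSE
    for (m in seq_along(retained)) {
      ref <- retained[[m]]$contacts
      rv <- if (length(ref) == 0) 0 else
        length(intersect(cand, ref)) / length(ref)
      if (rv > threshold) {
        retained[[m]]$P <- retained[[m]]$P + ord$P[r]
        retained[[m]]$merged_from <- c(retained[[m]]$merged_from, cl)
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      retained[[length(retained) + 1]] <-
        list(cluster = cl, snapshot = snap, P = ord$P[r], merged_from = cl,
             contacts = cand)
    }
  }
  P <- vapply(retained, `[[`, numeric(1), "P")
  cfe_new <- -GAS_CONSTANT * T * log(P)
  cfe_new <- cfe_new - min(cfe_new)
  ordi <- order(cfe_new)
  out <- data.frame(
    rank = seq_along(ordi),
    cluster = vapply(retained, `[[`, numeric(1), "cluster")[ordi],
    snapshot = vapply(retained, `[[`, numeric(1), "snapshot")[ordi],
    P = P[ordi], cfe = cfe_new[ordi],
    stable = cfe_new[ordi] < cfe_cutoff,
    merged_from = vapply(retained, function(x)
      paste(x$merged_from, collapse = ","), character(1))[ordi])
  structure(out, T = T, threshold = threshold, cfe_cutoff = cfe_cutoff,
            class = c("representative_set", "data.frame"))
}

#' Representative table in the standard report shape
#'
#' Augments a representative set with landscape coordinates (PC1, PC2), the
#' landscape free energy of the representative's bin, and optional
#' structural observables, mirroring the columns used to characterize
#' binding configurations.
#'
#' @param repset a [merge_by_rvalue()] result.
#' @param projection the landscape projection.
#' @param fel a [compute_fel()] landscape.
#' @return Data frame with one row per representative.
#' @export
representative_table <- function(repset, projection, fel = NULL) {
  snaps <- repset$snapshot
  out <- data.frame(rank = repset$rank, cfe = repset$cfe,
                    pc1 = projection$scores[snaps, 1],
                    pc2 = projection$scores[snaps, 2])
  if (!is.null(fel)) out$pca_fe <- fel_value(fel, out$pc1, out$pc2)
  out$P <- repset$P
  out$snapshot <- snaps
  out$stable <- repset$stable
  out
}
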