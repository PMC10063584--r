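test_that("k' = n makes every snapshot its own cluster", {
  set.seed(3)
  p <- pca_fit_project(matrix(rnorm(40), 20, 2))
  cl <- cluster_pc(p, 20, dims = 2, seed = 1)
  expect_equal(sort(unique(cl$labels)), 1:20)
  expect_equal(max(table(cl$labels)), 1)
})

test_that("K-means recovers planted modes and is deterministic", {
  pe <- make_planted_ensemble(list(
    list(mass = 0.5, assign = c(1, 2, 3, 4, 5)),
    list(mass = 0.3, assign = c(6, 7, 8, 1, 2)),
    list(mass = 0.2, assign = c(3, 6, 1, 8, 7))), n = 300, seed = 4)
  ts <- toy_structure(pe$ensemble$topology)
  spec <- selection_spec(ts,
                         receptor_anchors = select_atoms(ts, role = "receptor"),
                         ligand_atoms = select_atoms(ts, role = "ligand"))
  p <- pca_fit_project(build_distance_features(pe$ensemble, spec))
  cl <- cluster_pc(p, 30, dims = n_components(p), seed = 7)
  # majority-mapped purity against the planted labels
  purity <- mean(vapply(1:30, function(k) {
    members <- pe$truth$labels[cl$labels == k]
    if (length(members) == 0) return(1)
    max(table(members)) / length(members)
  }, numeric(1)))
  expect_gt(purity, 0.9)
  expect_identical(cluster_pc(p, 30, dims = n_components(p), seed = 7)$labels,
                   cl$labels)
  expect_error(cluster_pc(p, 1e6, seed = 1), "exceeds")
})

test_that("cluster free energies follow -RT ln P with ascending ranks", {
  labels <- c(rep(1, 40), rep(2, 20))
  cl <- structure(list(labels = labels, centroids = matrix(0, 2, 2),
                       k_prime = 2, dims = 2, seed = 1),
                  class = "cluster_set")
  w <- rep(1 / 60, 60)
  tab <- cluster_free_energy(cl, w, T = 300)
  expect_equal(tab$cfe[1], 0)
  expect_equal(tab$cfe[2], mcdock::GAS_CONSTANT * 300 * log(2),
               tolerance = 1e-9)
  expect_true(all(diff(tab$cfe) >= 0))
  # one cluster only
  cl1 <- structure(list(labels = rep(1, 10), centroids = matrix(0, 1, 2),
                        k_prime = 1, dims = 2, seed = 1),
                   class = "cluster_set")
  expect_equal(cluster_free_energy(cl1, rep(0.1, 10))$cfe, 0)
  # empty cluster flagged and excluded
  cl3 <- structure(list(labels = rep(1:2, 5), centroids = matrix(0, 3, 2),
                        k_prime = 3, dims = 2, seed = 1),
                   class = "cluster_set")
  expect_warning(t3 <- cluster_free_energy(cl3, rep(0.1, 10)), "empty")
  expect_equal(nrow(t3), 2)
})

test_that("representative picking is nearest-to-centroid with index ties", {
  set.seed(5)
  S <- matrix(rnorm(100), 50, 2)
  p <- structure(list(scores = S, contrib = c(60, 40),
                      rotation = diag(2), center = c(0, 0)),
                 class = "projection")
  cl <- cluster_pc(p, 3, dims = 2, seed = 2)
  reps <- pick_representatives(cl, p)
  for (k in 1:3) {
    members <- which(cl$labels == k)
    d2 <- rowSums(sweep(S[members, , drop = FALSE], 2, cl$centroids[k, ])^2)
    expect_equal(reps[k], members[which.min(d2)])  # brute-force scan
  }
  # singleton cluster is its own representative; equidistant tie -> lower index
  S2 <- rbind(c(-1, 0), c(1, 0), c(9, 9))
  p2 <- structure(list(scores = S2, contrib = c(60, 40), rotation = diag(2),
                       center = c(0, 0)), class = "projection")
  cl2 <- structure(list(labels = c(1, 1, 2), centroids = rbind(c(0, 0), c(9, 9)),
                        k_prime = 2, dims = 2, seed = 1),
                   class = "cluster_set")
  expect_equal(pick_representatives(cl2, p2), c(1, 3))
})

test_that("R-value merging collapses overlapping modes and conserves mass", {
  pe <- make_planted_ensemble(planted_five_modes(), n = 500, seed = 9)
  ts <- toy_structure(pe$ensemble$topology)
  spec <- selection_spec(ts,
                         receptor_anchors = select_atoms(ts, role = "receptor"),
                         ligand_atoms = select_atoms(ts, role = "ligand"))
  p <- pca_fit_project(build_distance_features(pe$ensemble, spec))
  cl <- cluster_pc(p, 25, dims = n_components(p), seed = 3)
  cfe <- cluster_free_energy(cl, pe$weights, T = 300)
  reps <- pick_representatives(cl, p)
  # overlap truth: exactly one pair of modes shares >70% of contacts
  expect_equal(sum(pe$truth$overlap[upper.tri(pe$truth$overlap)] > 0.7), 1)
  merged <- merge_by_rvalue(cfe, reps, pe$ensemble, threshold = 0.7,
                            cfe_cutoff = 2.5, T = 300)
  expect_equal(nrow(merged), 4)  # 5 planted modes, two of them merged
  expect_equal(sum(merged$P), sum(cfe$P), tolerance = 1e-12)
  expect_equal(min(merged$cfe), 0)
  expect_true(all(diff(merged$cfe) >= 0))
  # planted CFE differences: recovered vs -RT ln(mass ratio), merged pair pooled
  planted_mass <- pe$truth$masses
  pooled <- c(planted_mass[1:3], planted_mass[4] + planted_mass[5])
  cfe_expected <- -mcdock::GAS_CONSTANT * 300 * log(sort(pooled, TRUE))
  cfe_expected <- cfe_expected - min(cfe_expected)
  expect_equal(merged$cfe, cfe_expected, tolerance = 0.1)
  # idempotence: merging the merged set changes nothing
  cfe2 <- structure(data.frame(cluster = merged$cluster, P = merged$P,
                               cfe = merged$cfe, rank = merged$rank),
                    class = c("cfe_table", "data.frame"))
  reps2 <- rep(NA_integer_, max(merged$cluster))
  reps2[merged$cluster] <- merged$snapshot
  merged2 <- merge_by_rvalue(cfe2, reps2, pe$ensemble, threshold = 0.7,
                             cfe_cutoff = 2.5, T = 300)
  expect_equal(nrow(merged2), nrow(merged))
  expect_equal(merged2$P, merged$P, tolerance = 1e-12)
  expect_error(merge_by_rvalue(cfe, reps, pe$ensemble, threshold = 1.5),
               "threshold")
})

test_that("identical representatives merge; disjoint ones do not", {
  pe <- suppressWarnings(make_planted_ensemble(list(
    list(mass = 0.6, assign = c(1, 2, 3, 4, 5), spread = 1e-6),
    list(mass = 0.4, assign = c(1, 2, 3, 4, 5), spread = 1e-6)),
    n = 100, seed = 2))
  ts <- toy_structure(pe$ensemble$topology)
  cfe <- structure(data.frame(cluster = 1:2, P = c(0.6, 0.4), cfe = c(0, 0.24),
                              rank = 1:2), class = c("cfe_table", "data.frame"))
  m <- merge_by_rvalue(cfe, c(1, 60), pe$ensemble)
  expect_equal(nrow(m), 1)
  expect_equal(m$P, 1, tolerance = 1e-12)
  pe2 <- suppressWarnings(make_planted_ensemble(list(
    list(mass = 0.6, assign = c(1, 2, 3, 4, 5)),
    list(mass = 0.4, assign = c(6, 7, 8, 9, 10))), n = 100, seed = 2))
  m2 <- merge_by_rvalue(cfe, c(1, 60), pe2$ensemble)
  expect_equal(nrow(m2), 2)
})

test_that("desk-scale cluster-count default caps at 1000", {
  expect_equal(default_k_prime(50), 5L)
  expect_equal(default_k_prime(6e6), 1000L)
})
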