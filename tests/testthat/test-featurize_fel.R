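make_line_ensemble <- function() {
  # two atoms, two frames: 3 A apart then 4 A apart
  ensemble(rbind(c(0, 0, 0, 3, 0, 0),
                 c(0, 0, 0, 0, 4, 0)),
           energy = c(0, 0))
}

test_that("distance features follow the selection spec", {
  m <- structure_model(data.frame(
    id = 1:2, name = "CA", element = "C", resname = "BEA", resid = 1:2,
    chain = c("R", "L"), x = c(0, 3), y = 0, z = 0),
    c(R = "receptor", L = "ligand"))
  spec <- selection_spec(m, receptor_anchors = 1, ligand_atoms = 2)
  f <- build_distance_features(make_line_ensemble(), spec)
  expect_equal(as.numeric(f[, 1]), c(3, 4))
})

test_that("sequence-exclusion window retains exactly the distant pairs", {
  chain6 <- structure_model(data.frame(
    id = 1:6, name = "CA", element = "C", resname = "BEA", resid = 1:6,
    chain = "L", x = seq(0, 15, 3), y = 0, z = 0),
    c(L = "ligand"))
  spec <- selection_spec(chain6, ligand_atoms = 1:6, exclusion = 3,
                         intermolecular = FALSE)
  expect_equal(nrow(spec$pairs), 3)
  expect_equal(unname(spec$pairs),
               rbind(c(1L, 5L), c(1L, 6L), c(2L, 6L)))
  # brute-force oracle over all pairs
  brute <- NULL
  for (i in 1:5) for (j in (i + 1):6) if (abs(i - j) > 3) {
    brute <- rbind(brute, c(i, j))
  }
  expect_equal(unname(spec$pairs), brute)
})

test_that("features are invariant under per-frame rigid motion", {
  ct <- make_cryptic_toy()
  ts <- toy_structure(ct$system)
  spec <- selection_spec(ts,
                         receptor_anchors = select_atoms(ts, role = "receptor"),
                         ligand_atoms = select_atoms(ts, role = "ligand"))
  r <- run_canonical(ct$system, 400, 500, seed = 2, save_every = 50)
  f0 <- build_distance_features(r, spec)
  rot <- r
  for (s in seq_len(n_snapshots(r))) {
    m <- rotate_model(snapshot_structure(r, s), ax = 0.3 * s, shift = c(s, -s, 2))
    # rebuild the coordinate row in topology (particle) order
    xyz <- as.matrix(m$atoms[order(m$atoms$id), c("x", "y", "z")])
    rot$coords[s, ] <- as.vector(t(xyz))
  }
  f1 <- build_distance_features(rot, spec)
  expect_equal(f1, f0, tolerance = 1e-8)
})

test_that("PCA contributions, sign convention and determinism behave", {
  # data varying along a single direction -> PC1 carries 100%
  t1 <- seq(-1, 1, length.out = 50)
  X <- cbind(3 + t1, 5 - 2 * t1, 1 + 0.5 * t1)
  p <- pca_fit_project(X)
  expect_equal(p$contrib[1], 100, tolerance = 1e-8)
  expect_true(all(diff(p$contrib) <= 1e-12))
  expect_lte(sum(p$contrib), 100 + 1e-9)
  # largest-magnitude loading positive
  expect_gt(p$rotation[which.max(abs(p$rotation[, 1])), 1], 0)
  # deterministic bit-for-bit
  expect_identical(pca_fit_project(X)$scores, p$scores)
  # isotropic 2-D cloud: both components near 50%
  set.seed(13)
  G <- matrix(rnorm(2e4), ncol = 2)
  pg <- pca_fit_project(G)
  expect_lt(abs(pg$contrib[1] - 50), 3)
  expect_lt(abs(pg$contrib[2] - 50), 3)
  expect_error(pca_fit_project(matrix(1, 5, 3)), "zero variance")
  # reconstruction from all retained components
  Xc <- sweep(X, 2, p$center)
  expect_equal(p$scores %*% t(p$rotation), Xc, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("component count follows the cumulative-variance rule", {
  set.seed(2)
  X <- cbind(rnorm(500, sd = 10), rnorm(500, sd = 5), rnorm(500, sd = 1),
             rnorm(500, sd = 0.1))
  p <- pca_fit_project(X)
  m <- n_components(p, 90)
  expect_identical(m, which(cumsum(p$contrib) > 90)[1])
})

test_that("free-energy landscapes bin, normalize and flag correctly", {
  # two occupied bins with 2:1 mass at 300 K -> delta PMF = RT ln 2
  S <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(1.5, 0.5))
  w <- c(1 / 3, 1 / 3, 1 / 3)
  fel <- compute_fel(S, w, T = 300, edges = list(x = 0:2, y = 0:1))
  expect_equal(min(fel$pmf), 0)
  expect_equal(fel$pmf[2, 1] - fel$pmf[1, 1],
               mcdock::GAS_CONSTANT * 300 * log(2), tolerance = 1e-9)
  # all mass in one bin: that bin 0, everything else flagged
  fel1 <- compute_fel(rbind(c(0.5, 0.5)), 1, T = 300,
                      edges = list(x = 0:3, y = 0:3))
  expect_equal(fel1$pmf[1, 1], 0)
  expect_equal(sum(!fel1$flagged), 1)
  # cutoff flag: mass ratio big enough to exceed 5 kcal/mol
  p_small <- exp(-6 / (mcdock::GAS_CONSTANT * 300))
  S2 <- rbind(c(0.5, 0.5), c(1.5, 0.5))
  w2 <- c(1 - p_small, p_small) / (1 - p_small + p_small)
  fel2 <- compute_fel(S2, w2, T = 300, edges = list(x = 0:2, y = 0:1))
  expect_gt(fel2$pmf[2, 1], 5)
  expect_true(fel2$flagged[2, 1])
  expect_false(fel2$flagged[1, 1])
  # grid not covering the scores errors with suggested bounds
  expect_error(compute_fel(rbind(c(10, 10)), 1, T = 300,
                           edges = list(x = 0:2, y = 0:1)),
               "suggested bounds")
  expect_equal(fel_value(fel, 0.5, 0.5), 0)
})
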