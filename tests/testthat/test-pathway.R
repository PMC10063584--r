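test_that("window construction covers the range contiguously", {
  w <- make_windows(-2.5, 40, 2.5)
  expect_equal(nrow(w), 17)
  expect_equal(w$lo[1], -2.5)
  expect_equal(w$hi[17], 40)
  expect_true(all(abs(w$lo[-1] - w$hi[-17]) < 1e-12))
  expect_equal(nrow(make_windows(0, 1, 1)), 1)
  expect_error(make_windows(5, 5, 1), "exceed")
  expect_error(make_windows(0, 1, -1), "positive")
  # last window truncation
  wt <- make_windows(0, 5, 2)
  expect_equal(wt$hi[3], 5)
})

# deterministic funnel: ligand rigidly slides out of the groove with jitter
make_funnel <- function(n_per = 12, seed = 77) {
  ct <- make_cryptic_toy()
  sys <- ct$system
  set.seed(seed)
  shifts <- seq(0, 18, length.out = 14)
  coords <- NULL
  for (s in shifts) {
    for (rep in seq_len(n_per)) {
      x <- sys$coords0
      lig <- ct$oracle$ligand_index
      x[lig, 1] <- x[lig, 1] + s
      x[lig, ] <- x[lig, ] + matrix(rnorm(length(lig) * 3, 0, 0.35),
                                    length(lig), 3)
      coords <- rbind(coords, as.vector(t(x)))
    }
  }
  ensemble(coords, energy = rep(0, nrow(coords)), topology = sys)
}

test_that("pathway picks maximize R against the previous pick (brute force)", {
  ens <- make_funnel()
  lambda <- lambda_series(ens)
  win <- make_windows(min(lambda) - 0.1, max(lambda) + 0.1, 2.5)
  start <- which.min(lambda)
  path <- extract_pathway(ens, lambda, start, win)
  expect_equal(path$snapshot[1], start)
  # every pick's lambda lies in its window (monotone by construction)
  expect_true(all(path$lambda >= path$lo & path$lambda <= path$hi))
  # brute-force per-window scan with contact_set-based R values
  for (k in 2:nrow(path)) {
    prev <- snapshot_structure(ens, path$snapshot[k - 1])
    members <- which(lambda >= path$lo[k] & lambda < path$hi[k])
    if (k == nrow(path)) {
      members <- which(lambda >= path$lo[k] & lambda <= path$hi[k])
    }
    rv <- vapply(members, function(s) {
      r <- tryCatch(brute_r_value(snapshot_structure(ens, s), prev),
                    error = function(e) 0)
      if (is.nan(r)) 0 else r   # reference without contacts scores 0
    }, numeric(1))
    expect_equal(path$r_prev[k], max(rv), tolerance = 1e-12)
    expect_true(path$snapshot[k] %in% members[rv == max(rv)])
  }
  # determinism
  path2 <- extract_pathway(ens, lambda, start, win)
  expect_identical(path$snapshot, path2$snapshot)
})

test_that("pathway errors are informative", {
  ens <- make_funnel(n_per = 2)
  lambda <- lambda_series(ens)
  win <- make_windows(min(lambda) - 0.1, max(lambda) + 30, 2.5)
  expect_error(extract_pathway(ens, lambda, which.min(lambda), win),
               "no snapshots")
  expect_error(extract_pathway(ens, lambda, which.max(lambda), win),
               "first window")
  expect_error(extract_pathway(ens, lambda[1:3], 1, win), "one value per")
})

test_that("single-member windows are picked trivially", {
  ct <- make_cryptic_toy()
  sys <- ct$system
  coords <- NULL
  for (s in c(0, 3, 6)) {
    x <- sys$coords0
    x[ct$oracle$ligand_index, 1] <- x[ct$oracle$ligand_index, 1] + s
    coords <- rbind(coords, as.vector(t(x)))
  }
  ens <- ensemble(coords, rep(0, 3), topology = sys)
  lambda <- lambda_series(ens)
  win <- make_windows(min(lambda) - 0.1, max(lambda) + 0.1, 3)
  path <- extract_pathway(ens, lambda, 1, win)
  expect_equal(path$snapshot, 1:3)
})

test_that("neighbor-similarity table flags low-R steps as barriers", {
  ens <- make_funnel()
  lambda <- lambda_series(ens)
  win <- make_windows(min(lambda) - 0.1, max(lambda) + 0.1, 2.5)
  path <- extract_pathway(ens, lambda, which.min(lambda), win)
  sim <- window_similarity(path, flag_threshold = 0.6)
  expect_equal(nrow(sim), nrow(path) - 1)
  expect_identical(sim$barrier, sim$r < 0.6)
  # identical consecutive picks give R = 1, RMSD = 0: duplicate one frame
  dup <- ensemble(ens$coords[c(1, 1), ], c(0, 0), topology = ens$topology)
  lam2 <- lambda_series(dup) + c(0, 2.5)  # force into adjacent windows
  w2 <- make_windows(lam2[1] - 0.1, lam2[2] + 0.1, 2.5)
  p2 <- extract_pathway(dup, lam2, 1, w2)
  expect_equal(p2$r_prev[2], 1)
  expect_equal(p2$rmsd_prev[2], 0)
})
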