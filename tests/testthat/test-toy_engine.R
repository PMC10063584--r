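test_that("restraint energies are zero in the flat region and quadratic outside", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0))
  fb <- restraint_spec("flat_bottom_distance", i = 1, j = 2, lo = 0, hi = 4.5,
                       k = 10)
  expect_equal(restraint_energy(coords, fb), 0)
  coords2 <- rbind(c(0, 0, 0), c(5.5, 0, 0))
  expect_equal(restraint_energy(coords2, fb), 10 * 1.0^2)  # k * delta^2
  cb <- restraint_spec("com_axis_box", group = 1:2, lo = -2.5, hi = 40,
                       k = 10, axis = 1)
  com10 <- rbind(c(8, 0, 0), c(12, 99, -99))  # COM x = 10, y/z ignored
  expect_equal(restraint_energy(com10, cb, masses = c(1, 1)), 0)
  com42 <- rbind(c(41, 0, 0), c(43, 0, 0))
  expect_equal(restraint_energy(com42, cb, masses = c(1, 1)), 10 * 4)
  expect_error(restraint_spec("flat_bottom_distance", i = 1, j = 2,
                              lo = 5, hi = 1, k = 1), "lower bound")
})

test_that("analytic gradients match central finite differences", {
  ct <- make_cryptic_toy()
  sys <- ct$system
  set.seed(5)
  x <- sys$coords0 + matrix(rnorm(3 * sys$n, 0, 0.3), sys$n, 3)
  g <- toy_gradient(sys, x)
  h <- 1e-5
  for (trial in 1:25) {
    i <- sample(sys$n, 1); ax <- sample(3, 1)
    xp <- x; xm <- x
    xp[i, ax] <- xp[i, ax] + h
    xm[i, ax] <- xm[i, ax] - h
    fd <- (toy_energy(sys, xp) - toy_energy(sys, xm)) / (2 * h)
    denom <- max(abs(fd), 1)
    expect_lt(abs(fd - g[i, ax]) / denom, 1e-5)
  }
})

test_that("kernel energies agree with the R-side potential", {
  ct <- make_cryptic_toy()
  r <- run_canonical(ct$system, 500, 200, seed = 3, save_every = 20)
  for (s in seq_len(n_snapshots(r))) {
    x <- matrix(r$coords[s, ], ncol = 3, byrow = TRUE)
    expect_equal(r$energy[s], toy_energy(ct$system, x), tolerance = 1e-8)
  }
})

test_that("canonical sampling reproduces equipartition in a harmonic well", {
  sys <- toy_system(matrix(0, 1, 3), mobile = c(TRUE),
                    terms = list(harm = rbind(c(1, 1, 0.5, 0),  # U = x^2/2...
                                              c(1, 2, 0.5, 0),
                                              c(1, 3, 0.5, 0))))
  T <- 300
  r <- run_canonical(sys, T, 2e5, seed = 9, save_every = 4, step = 0.8)
  # 3 dof, U = sum k x^2 with k = 1/2: <U> = 3RT/2 * (1/2)... equipartition:
  # each quadratic dof contributes RT/2 -> <U> = 3RT/2
  expected <- 1.5 * mcdock::GAS_CONSTANT * T
  se <- stats::sd(r$energy) / sqrt(n_snapshots(r) / 20)  # crude decorrelation
  expect_lt(abs(mean(r$energy) - expected), 3 * se + 0.01)
})

test_that("same seed gives bitwise-identical trajectories, quench descends", {
  dw <- make_double_well(4, 1, 1)
  a <- run_canonical(dw$system, 300, 3000, seed = 42)
  b <- run_canonical(dw$system, 300, 3000, seed = 42)
  expect_identical(a$energy, b$energy)
  expect_identical(a$coords, b$coords)
  q <- run_canonical(dw$system, 300, 2000, seed = 1, save_every = 10,
                     quench = TRUE, coords0 = matrix(c(3.5, 0, 0), 1, 3))
  expect_true(all(diff(q$energy) <= 1e-12))
})

test_that("sampler matches the canonical distribution (degenerate bias)", {
  dw <- make_double_well(3, 0, 1)
  # widely spaced frames so the two-sample KS test sees near-independent draws
  mc <- run_mcmd(dw$system, bias_identity(500), 2e5, seed = 2,
                 save_every = 40, step = 0.4)
  ca <- run_canonical(dw$system, 500, 2e5, seed = 77, save_every = 40,
                      step = 0.4)
  ks <- suppressWarnings(stats::ks.test(mc$coords[, 1], ca$coords[, 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("initial bias estimation needs enough energy bins", {
  # constant-energy degenerate input
  e <- ensemble(matrix(rnorm(50), 50, 1), energy = rep(1, 50))
  expect_error(estimate_initial_bias(e, mcmd_config()), "bins")
})

test_that("bias update is a fixed point on a flat histogram and penalizes over-sampling", {
  cfg <- mcmd_config(bin_width = 0.5)
  grid <- seq(0, 10, by = 0.5)
  bias0 <- bias_function(grid, grid, T_mc = 700)   # identity on a grid
  # perfectly flat occupancy over [0, 10]
  set.seed(1)
  E_flat <- rep(seq(0.25, 9.75, by = 0.5), each = 400)
  ens_flat <- ensemble(matrix(0, length(E_flat), 1), energy = E_flat)
  b1 <- update_bias(bias0, ens_flat, cfg, smooth_df = 3)
  mid <- b1$E_grid > 1 & b1$E_grid < 9
  delta <- bias_value(b1, b1$E_grid[mid]) - bias_value(bias0, b1$E_grid[mid])
  expect_lt(max(delta) - min(delta), 0.05)  # constant shift only
  # doubling one bin's population raises its modified energy by R*T*ln 2
  E_bump <- c(E_flat, rep(5.25, 400))
  ens_bump <- ensemble(matrix(0, length(E_bump), 1), energy = E_bump)
  b2 <- update_bias(bias0, ens_bump, cfg, smooth_df = 19)
  base <- bias_value(b2, 2.25) - bias_value(b1, 2.25)
  raise <- (bias_value(b2, 5.25) - bias_value(b1, 5.25)) - base
  expect_equal(raise, mcdock::GAS_CONSTANT * 700 * log(2), tolerance = 0.25)
})

test_that("bias updates preserve monotonicity of the modified energy", {
  dw <- make_double_well(4, 1, 2)
  cfg <- mcmd_config(bin_width = 0.1, init_sweeps = 5e4,
                     schedule = c(5e4, 5e4), max_iter = 2)
  seed_run <- run_canonical(dw$system, 700, 5e4, seed = 8, save_every = 2,
                            step = 0.35)
  b <- suppressWarnings(estimate_initial_bias(seed_run, cfg))
  expect_true(all(diff(b$E_mc) >= -1e-9))
  r <- run_mcmd(dw$system, b, 5e4, seed = 9, save_every = 2, step = 0.35)
  b2 <- suppressWarnings(update_bias(b, r, cfg))
  expect_true(all(diff(b2$E_mc) >= -1e-9))
})

test_that("multiple seeds give distinct parallel trajectories", {
  dw <- make_double_well(4, 0, 1)
  r <- run_mcmd(dw$system, bias_identity(400), 1000, seed = 5,
                n_parallel = 4, save_every = 10)
  expect_equal(length(unique(r$traj)), 4)
  e_by_traj <- split(r$energy, r$traj)
  expect_false(identical(e_by_traj[[1]], e_by_traj[[2]]))
})
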