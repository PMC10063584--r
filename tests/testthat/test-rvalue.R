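test_that("contact sets match cutoff geometry and the brute-force oracle", {
  mk <- function(d) structure_model(data.frame(
    id = 1:2, name = "CA", element = "C", resname = "BEA", resid = c(1, 1),
    chain = c("A", "B"), x = c(0, d), y = 0, z = 0),
    c(A = "receptor", B = "ligand"))
  expect_length(contact_set(mk(4.0), "inter"), 1)
  expect_length(contact_set(mk(4.6), "inter"), 0)
  # 20 random atoms vs O(n^2) brute force, all scopes
  set.seed(21)
  m <- structure_model(data.frame(
    id = 1:20, name = "CA", element = sample(c("C", "N", "O", "H"), 20, TRUE),
    resname = "BEA", resid = rep(1:10, 2), chain = rep(c("A", "B"), each = 10),
    x = runif(20, 0, 12), y = runif(20, 0, 12), z = runif(20, 0, 12)),
    c(A = "receptor", B = "ligand"))
  for (sc in c("inter", "intra", "both")) {
    expect_setequal(as.character(contact_set(m, sc)), brute_contacts(m, sc))
  }
})

test_that("R-value identities, halves and asymmetry", {
  m <- two_chain_model()
  expect_equal(r_value(m, m, scope = "inter"), 1.0)
  expect_equal(r_value(m, m, scope = "both"), 1.0)
  # move the ligand far away: no reference contact survives
  far <- m
  far$atoms$x[far$atoms$chain == "B"] <- far$atoms$x[far$atoms$chain == "B"] + 100
  expect_equal(r_value(far, m, scope = "inter"), 0)
  expect_error(r_value(m, far, scope = "inter"), "undefined|no contacts")
  # constructed case preserving exactly 3 of 6 reference contacts:
  # 6 ligand beads each touching one well-separated receptor bead
  a <- data.frame(id = 1:12, name = "CA", element = "C", resname = "BEA",
                  resid = c(1:6, 1:6),
                  chain = rep(c("A", "B"), each = 6),
                  x = c(seq(0, 50, 10), seq(0, 50, 10)),
                  y = c(rep(0, 6), rep(3, 6)), z = 0)
  ref <- structure_model(a, c(A = "receptor", B = "ligand"))
  expect_length(contact_set(ref, "inter"), 6)
  q <- ref
  q$atoms$y[7:9] <- 50  # break the first three ligand contacts
  expect_equal(r_value(q, ref, "inter"), 0.5)
  expect_equal(brute_r_value(q, ref, "inter"), 0.5)
  # asymmetry: q as reference has only 3 contacts, all preserved in ref
  expect_equal(r_value(ref, q, "inter"), 1.0)
})

test_that("R-value is monotone non-increasing under progressive contact loss", {
  set.seed(31)
  a <- data.frame(id = 1:16, name = "CA", element = "C", resname = "BEA",
                  resid = c(1:8, 1:8), chain = rep(c("A", "B"), each = 8),
                  x = c(seq(0, 70, 10), seq(0, 70, 10)),
                  y = c(rep(0, 8), rep(3, 8)), z = 0)
  ref <- structure_model(a, c(A = "receptor", B = "ligand"))
  q <- ref
  rv <- r_value(q, ref, "inter")
  for (k in sample(9:16)) {
    q$atoms$y[k] <- 80
    rv_new <- r_value(q, ref, "inter")
    expect_lte(rv_new, rv + 1e-12)
    rv <- rv_new
  }
  expect_equal(rv, 0)
})

test_that("per-residue decomposition is local and averages to the global R", {
  a <- data.frame(id = 1:12, name = "CA", element = "C", resname = "BEA",
                  resid = c(1:6, 1:6), chain = rep(c("A", "B"), each = 6),
                  x = c(seq(0, 50, 10), seq(0, 50, 10)),
                  y = c(rep(0, 6), rep(3, 6)), z = 0)
  ref <- structure_model(a, c(A = "receptor", B = "ligand"))
  expect_true(all(per_residue_r_value(ref, ref, "inter")$r == 1))
  q <- ref
  q$atoms$y[11] <- 80  # perturb only ligand residue 5
  rep5 <- per_residue_r_value(q, ref, "inter")
  expect_equal(rep5$r[rep5$resid == 5], 0)
  expect_true(all(rep5$r[rep5$resid != 5] == 1))
  # contact-weighted mean equals the global value
  g <- attr(rep5, "global")
  ok <- !is.na(rep5$r)
  expect_equal(sum(rep5$r[ok] * rep5$n_ref_contacts[ok]) /
                 sum(rep5$n_ref_contacts[ok]), g)
  expect_equal(g, r_value(q, ref, "inter"))
})

test_that("RMSD identities, superposition and the quaternion oracle agree", {
  m <- two_chain_model()
  expect_equal(rmsd(m, m), 0)
  shifted <- m
  shifted$atoms$x <- shifted$atoms$x + 7
  expect_lt(rmsd(shifted, m, superpose = TRUE), 1e-9)
  expect_equal(rmsd(shifted, m, superpose = FALSE), 7)
  # 4-point sets with optimal alignment vs independent quaternion method
  set.seed(8)
  for (trial in 1:5) {
    P <- matrix(rnorm(12), 4, 3)
    Q <- matrix(rnorm(12), 4, 3)
    mp <- structure_model(data.frame(id = 1:4, name = "CA", element = "C",
                                     resname = "BEA", resid = 1:4, chain = "A",
                                     x = P[, 1], y = P[, 2], z = P[, 3]))
    mq <- structure_model(data.frame(id = 1:4, name = "CA", element = "C",
                                     resname = "BEA", resid = 1:4, chain = "A",
                                     x = Q[, 1], y = Q[, 2], z = Q[, 3]))
    expect_equal(rmsd(mp, mq, superpose = TRUE), quaternion_rmsd(P, Q),
                 tolerance = 1e-6)
  }
  # invariance under proper rigid motion of either input
  r1 <- rmsd(rotate_model(m, 0.8, 0.1, -0.5, c(1, 2, 3)), m)
  expect_lt(r1, 1e-9)
  mm <- m; mm$atoms$z[3] <- mm$atoms$z[3] + 2
  base <- rmsd(mm, m)
  expect_equal(rmsd(rotate_model(mm), m), base, tolerance = 1e-9)
  expect_equal(rmsd(mm, rotate_model(m)), base, tolerance = 1e-9)
})

test_that("RMSD agrees with the bio3d reference implementation", {
  set.seed(12)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P + matrix(rnorm(30, 0, 0.5), 10, 3)
  mp <- structure_model(data.frame(id = 1:10, name = "CA", element = "C",
                                   resname = "BEA", resid = 1:10, chain = "A",
                                   x = P[, 1], y = P[, 2], z = P[, 3]))
  mq <- structure_model(data.frame(id = 1:10, name = "CA", element = "C",
                                   resname = "BEA", resid = 1:10, chain = "A",
                                   x = Q[, 1], y = Q[, 2], z = Q[, 3]))
  ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(rmsd(mp, mq, superpose = TRUE), ref, tolerance = 1e-4)
})
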