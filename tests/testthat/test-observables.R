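read_dssp_reference <- function() {
  f <- system.file("extdata", "dssp_reference_labels.tsv", package = "mcdock")
  utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

build_fixture <- function(name) {
  switch(name,
         helix = build_peptide(15, -57, -47),
         ext = build_peptide(15, 180, 180),
         g310 = build_peptide(15, -49, -26),
         coil = {
           set.seed(42)
           build_peptide(20, stats::runif(20, -180, 180),
                         stats::runif(20, -180, 180))
         })
}

map4 <- function(x) ifelse(x %in% c("H", "G", "E"), x, "C")

test_that("secondary structure matches the reference DSSP labels (>= 98%)", {
  ref <- read_dssp_reference()
  agree <- 0; total <- 0
  for (fx in unique(ref$fixture)) {
    m <- build_fixture(fx)
    ours <- map4(unname(assign_ss(m)))
    theirs <- map4(ref$dssp[ref$fixture == fx])
    expect_equal(length(ours), length(theirs))
    agree <- agree + sum(ours == theirs)
    total <- total + length(ours)
  }
  expect_gte(agree / total, 0.98)
})

test_that("helix interiors are H, extended chains have no H, termini never H", {
  ss_h <- assign_ss(build_peptide(15, -57, -47))
  expect_true(all(ss_h[3:12] == "H"))
  expect_equal(unname(ss_h[1]), "C")
  expect_equal(unname(ss_h[15]), "C")
  expect_false(any(assign_ss(build_peptide(15, 180, 180)) == "H"))
  # 3-10 helix labelled G, not H
  ss_g <- assign_ss(build_peptide(15, -49, -26))
  expect_true(all(ss_g[4:11] == "G"))
  expect_false(any(ss_g == "H"))
})

test_that("missing backbone atoms degrade gracefully to C", {
  m <- build_peptide(8, -57, -47)
  m$atoms <- m$atoms[!(m$atoms$resid == 4 & m$atoms$name == "O"), ]
  expect_warning(ss <- assign_ss(m), "missing backbone")
  expect_equal(unname(ss[4]), "C")
})

test_that("helicity profiles are weight-averaged per residue", {
  # two snapshots of a 12-residue chain: helix and extended, weights 3:1
  h <- build_peptide(12, -57, -47)
  e <- build_peptide(12, 180, 180)
  xyz <- function(m) as.vector(t(as.matrix(m$atoms[, c("x", "y", "z")])))
  ens <- ensemble(rbind(xyz(h), xyz(e)), c(0, 0), topology = h)
  w <- structure(list(w = c(0.75, 0.25), T = 300, ess = 1.6, log_w = c(0, 0)),
                 class = "weight_vector")
  prof <- helicity_profile(ens, w, chain = "A")
  expect_equal(unname(prof[6]), 0.75)
  expect_equal(unname(prof[1]), 0)
  all_h <- helicity_profile(ensemble(rbind(xyz(h), xyz(h)), c(0, 0),
                                     topology = h),
                            structure(list(w = c(0.5, 0.5), T = 300,
                                           ess = 2, log_w = c(0, 0)),
                                      class = "weight_vector"), chain = "A")
  expect_true(all(all_h[4:9] == 1))
})

test_that("Shrake-Rupley areas match closed forms and a refined oracle", {
  one <- structure_model(data.frame(id = 1, name = "CA", element = "C",
                                    resname = "BEA", resid = 1, chain = "A",
                                    x = 0, y = 0, z = 0))
  s1 <- sasa(one, probe = 1.4, n_points = 960)
  expect_equal(s1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # far-separated atoms are additive
  two <- structure_model(data.frame(id = 1:2, name = "CA", element = "C",
                                    resname = "BEA", resid = 1:2, chain = "A",
                                    x = c(0, 50), y = 0, z = 0))
  expect_equal(sasa(two)$total, 2 * s1$total, tolerance = 1e-6)
  # overlapping spheres vs high-resolution refinement of the same construction
  ov <- structure_model(data.frame(id = 1:2, name = c("CA", "N"),
                                   element = c("C", "N"), resname = "BEA",
                                   resid = 1:2, chain = "A",
                                   x = c(0, 2.2), y = 0, z = 0))
  coarse <- sasa(ov, n_points = 960)$total
  fine <- sasa(ov, n_points = 1e5)$total
  expect_lt(abs(coarse - fine) / fine, 0.02)
  expect_error(sasa(structure_model(data.frame(
    id = 1, name = "XX", element = "Xx", resname = "UNK", resid = 1,
    chain = "A", x = 0, y = 0, z = 0))), "radius")
})

test_that("relative accessibility spans exposed to buried and is rigid-motion invariant", {
  lig <- data.frame(id = 1, name = "CA", element = "C", resname = "BEA",
                    resid = 1, chain = "L", x = 0, y = 0, z = 0)
  far <- structure_model(rbind(
    data.frame(id = 2, name = "CA", element = "C", resname = "BEA",
               resid = 1, chain = "R", x = 60, y = 0, z = 0), lig),
    c(R = "receptor", L = "ligand"))
  expect_equal(rasa(far), 1.0, tolerance = 1e-9)
  # dense cage of receptor atoms around the ligand buries it
  g <- expand.grid(x = seq(-3, 3, 1.5), y = seq(-3, 3, 1.5),
                   z = seq(-3, 3, 1.5))
  g <- g[sqrt(g$x^2 + g$y^2 + g$z^2) > 1.9, ]
  cage <- structure_model(rbind(
    data.frame(id = seq_len(nrow(g)) + 1, name = "CA", element = "C",
               resname = "BEA", resid = seq_len(nrow(g)), chain = "R",
               x = g$x, y = g$y, z = g$z), lig),
    c(R = "receptor", L = "ligand"))
  expect_lt(rasa(cage), 0.05)
  expect_equal(rasa(rotate_model(cage)), rasa(cage), tolerance = 1e-9)
})

test_that("pocket distances and the dissociation coordinate evaluate directly", {
  a <- data.frame(id = 1:3, name = "CA", element = "C", resname = "BEA",
                  resid = 1:3, chain = "R",
                  x = c(0, 3, 0), y = c(0, 4, 0), z = 0)
  m <- structure_model(a, c(R = "receptor"))
  d <- pocket_distances(m, data.frame(res_i = 1, res_j = 2))
  expect_equal(unname(d["d0"]), 5)
  expect_error(pocket_distances(m, data.frame(res_i = 1, res_j = 99)),
               "resolve")
  # lambda: single unit-mass atom at x = 7, then two-atom mean
  lig1 <- structure_model(data.frame(id = 1, name = "CA", element = "C",
                                     resname = "BEA", resid = 1, chain = "L",
                                     x = 7, y = 1, z = 2),
                          c(L = "ligand"))
  expect_equal(lambda_coord(lig1), 7)
  lig2 <- structure_model(data.frame(id = 1:2, name = "CA", element = "C",
                                     resname = "BEA", resid = 1:2, chain = "L",
                                     x = c(0, 10), y = 0, z = 0),
                          c(L = "ligand"))
  expect_equal(lambda_coord(lig2), 5)
})

test_that("lambda_series matches per-snapshot lambda_coord", {
  ct <- make_cryptic_toy()
  r <- run_canonical(ct$system, 500, 400, seed = 6, save_every = 40)
  lam <- lambda_series(r)
  for (s in seq_len(n_snapshots(r))) {
    expect_equal(lam[s], lambda_coord(snapshot_structure(r, s)),
                 tolerance = 1e-9)
  }
})

test_that("high-temperature reweighted pocket distributions are flatter", {
  # the gate-coordinate distribution loses structure as the reweighting
  # temperature rises: sharp state preference at 300 K, near-random at 700 K
  ct <- make_cryptic_toy()
  fl <- suppressWarnings(iterate_bias(ct$system, mcmd_config(), seed = 5))
  run <- run_mcmd(ct$system, fl$bias, 4e4, seed = 51, save_every = 4,
                  step = 0.35)
  gate_y <- run$coords[, 3 * (ct$oracle$gate_index - 1) + 2]
  edges <- seq(min(gate_y) - 0.1, max(gate_y) + 0.1, length.out = 20)
  entropy <- function(d) { p <- d$mass[d$mass > 0]; -sum(p * log(p)) }
  ent <- vapply(c(300, 500, 700), function(T) {
    w <- suppressWarnings(canonical_weights(run, fl$bias, T))
    entropy(reweighted_histogram(gate_y, w, edges))
  }, numeric(1))
  expect_true(all(diff(ent) > 0))
})
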