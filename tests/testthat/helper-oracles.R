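# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force loops, quaternion superposition and
# quadrature only.

# Quaternion-method optimal-superposition RMSD (independent of the package's
# SVD-based Kabsch implementation).
quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Q, P)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# O(n^2) brute-force contact enumeration with explicit loops.
brute_contacts <- function(model, scope = "inter", cutoff = 4.5) {
  a <- model$atoms
  out <- character(0)
  for (i in seq_len(nrow(a) - 1)) {
    if (toupper(a$element[i]) == "H") next
    for (j in (i + 1):nrow(a)) {
      if (toupper(a$element[j]) == "H") next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d > cutoff) next
      ri <- model$chain_roles[[a$chain[i]]]
      rj <- model$chain_roles[[a$chain[j]]]
      is_inter <- ri != rj
      is_intra <- a$chain[i] == a$chain[j] && abs(a$resid[i] - a$resid[j]) > 2
      keep <- switch(scope, inter = is_inter, intra = is_intra,
                     both = is_inter || is_intra)
      if (keep) out <- c(out, paste0(i, "-", j))
    }
  }
  out
}

brute_r_value <- function(model, reference, scope = "inter", cutoff = 4.5) {
  cr <- brute_contacts(reference, scope, cutoff)
  cq <- brute_contacts(model, scope, cutoff)
  length(intersect(cq, cr)) / length(cr)
}

# tiny two-chain complex used by structure / contact / rmsd tests:
# receptor chain A, 4 residues; ligand chain B, 2 residues.
two_chain_pdb <- function() {
  c("HEADER    TEST FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       3.800   1.500   0.000  1.00  0.00           C",
    "ATOM      5  CA  SER A   3       5.500   2.900   0.500  1.00  0.00           C",
    "ATOM      6  OG  SER A   3       6.000   3.500   1.500  1.00  0.00           O",
    "ATOM      7  CA  VAL A   4       7.900   3.100   0.000  1.00  0.00           C",
    "TER",
    "ATOM      8  CA  LEU B   1       2.000   3.000   0.500  1.00  0.00           C",
    "ATOM      9  CB  LEU B   1       2.500   4.200   0.800  1.00  0.00           C",
    "ATOM     10  CA  ILE B   2       5.200   4.100   0.200  1.00  0.00           C",
    "END")
}

two_chain_model <- function() {
  read_structure(two_chain_pdb(), chain_roles = c(A = "receptor", B = "ligand"))
}

# rigid rotation + translation helper (proper rotation)
rotate_model <- function(model, ax = 0.4, ay = -0.7, az = 1.1,
                         shift = c(3, -2, 5)) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)),
               3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  U <- Rz %*% Ry %*% Rx
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(U)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

# standard planted 5-mode spec: modes 4 and 5 share 4/5 bead assignments
# (80% contact overlap > the 0.7 merge threshold); all other pairs share
# at most 1/5.
planted_five_modes <- function() {
  list(list(mass = 0.30, assign = c(1, 2, 3, 4, 5)),
       list(mass = 0.25, assign = c(6, 7, 8, 1, 2)),
       list(mass = 0.20, assign = c(3, 6, 1, 8, 7)),
       list(mass = 0.15, assign = c(2, 4, 6, 7, 3)),
       list(mass = 0.10, assign = c(2, 4, 6, 7, 8)))
}
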