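# Internal-coordinate (NeRF) placement: position D given A-B-C with bond
# |CD|, angle B-C-D (degrees) and torsion A-B-C-D (degrees).
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone from backbone dihedrals
#'
#' Generates N, CA, C, O backbone coordinates for an `n`-residue
#' poly-alanine chain from phi/psi (and omega) dihedrals using standard
#' bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231
#' Angstrom; N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees). `phi` and
#' `psi` may be scalars (ideal repeats: alpha-helix -57/-47, 3-10 helix
#' -49/-26, extended 180/180) or length-`n` vectors (e.g. a random coil).
#' Deterministic: no randomness is used.
#'
#' @param n residue count.
#' @param phi,psi backbone dihedrals in degrees.
#' @param omega peptide-bond dihedral (default 180, trans).
#' @param chain chain id.
#' @return A [structure_model()] with 4 backbone atoms per residue.
#' @export
build_peptide <- function(n, phi = -57, psi = -47, omega = 180, chain = "A") {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  C[1, ] <- place_atom(c(-1, 1, 0), N[1, ], CA[1, ], b_CAC, a_NCAC, phi[1])
  for (r in 2:n) {
    N[r, ] <- place_atom(N[r - 1, ], CA[r - 1, ], C[r - 1, ], b_CN, a_CACN,
                         psi[r - 1])
    CA[r, ] <- place_atom(CA[r - 1, ], C[r - 1, ], N[r, ], b_NCA, a_CNCA,
                          omega[r - 1])
    C[r, ] <- place_atom(C[r - 1, ], N[r, ], CA[r, ], b_CAC, a_NCAC, phi[r])
  }
  for (r in 1:n) {
    # carbonyl O in the peptide plane, anti to the following N (torsion
    # N-CA-C-O = psi + 180)
    O[r, ] <- place_atom(N[r, ], CA[r, ], C[r, ], b_CO, a_CACO,
                         psi[r] + 180)
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(r) {
    data.frame(id = 4 * (r - 1) + 1:4, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"), resname = "ALA",
               resid = r, chain = chain,
               x = c(N[r, 1], CA[r, 1], C[r, 1], O[r, 1]),
               y = c(N[r, 2], CA[r, 2], C[r, 2], O[r, 2]),
               z = c(N[r, 3], CA[r, 3], C[r, 3], O[r, 3]),
               stringsAsFactors = FALSE)
  }))
  structure_model(atoms, stats::setNames("receptor", chain))
}
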