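#' Physical constants and bundled lookup tables
#'
#' All energies in the package are in kcal/mol, distances in Angstrom and
#' temperatures in Kelvin. `GAS_CONSTANT` is the molar gas constant R in
#' kcal/mol/K; every Boltzmann factor and free-energy formula uses it.
#'
#' @format `GAS_CONSTANT` is a length-one numeric.
#' @export
GAS_CONSTANT <- 1.98720425864083e-3

#' Residue template atom counts
#'
#' Atom counts (hydrogens included) of the Amber-style all-hydrogen residue
#' templates at neutral pH for the 20 standard amino acids plus the ACE
#' (acetyl) and NHE (amide) capping groups. Histidine uses the neutral HIE
#' tautomer. These counts reproduce published peptide system compositions,
#' e.g. a capped 18-mer BH3 peptide totals 319 atoms.
#'
#' @return Named integer vector keyed by three-letter residue code.
#' @seealso [count_atoms()]
#' @export
residue_template_table <- function() {
  c(ALA = 10L, ARG = 24L, ASN = 14L, ASP = 12L, CYS = 11L,
    GLN = 17L, GLU = 15L, GLY = 7L,  HIS = 17L, ILE = 19L,
    LEU = 19L, LYS = 22L, MET = 17L, PHE = 20L, PRO = 14L,
    SER = 11L, THR = 14L, TRP = 24L, TYR = 21L, VAL = 16L,
    ACE = 6L,  NHE = 3L)
}

# One-letter -> three-letter residue code map used by count_atoms().
AA_CODE_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Van der Waals radii by element
#'
#' Bondi (1964) van der Waals radii in Angstrom for the elements occurring in
#' protein heavy atoms plus hydrogen. Used by [sasa()]; bundled so that
#' accessibility values are reproducible across installations.
#'
#' @return Named numeric vector keyed by element symbol.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

# Standard atomic masses (g/mol) for center-of-mass coordinates.
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

element_mass <- function(element) {
  m <- ATOMIC_MASSES[toupper(element)]
  if (anyNA(m)) {
    stop("no mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
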