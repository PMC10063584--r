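#' Structural model of a receptor-ligand complex
#'
#' A `structure_model` holds the atoms of one or more chains together with an
#' assignment of each chain to a role (`"receptor"` or `"ligand"`). Atoms are
#' stored as a data frame with columns `id`, `name`, `element`, `resname`,
#' `resid`, `chain`, `x`, `y`, `z` (coordinates in Angstrom) and optionally
#' `radius`.
#'
#' @param atoms data frame with the columns listed above.
#' @param chain_roles named character vector mapping chain id to role; when
#'   omitted, all chains default to `"receptor"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, chain_roles = NULL) {
  required <- c("id", "name", "element", "resname", "resid", "chain",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in structure")
  }
  chains <- unique(atoms$chain)
  if (is.null(chain_roles)) {
    chain_roles <- stats::setNames(rep("receptor", length(chains)), chains)
  }
  if (!all(chains %in% names(chain_roles))) {
    stop("chain_roles does not cover chain(s): ",
         paste(setdiff(chains, names(chain_roles)), collapse = ", "))
  }
  if (!all(chain_roles %in% c("receptor", "ligand"))) {
    stop("chain roles must be 'receptor' or 'ligand'")
  }
  # residue indices must be strictly increasing within each chain
  for (ch in chains) {
    r <- atoms$resid[atoms$chain == ch]
    if (any(diff(r) < 0)) {
      stop("residue indices not non-decreasing within chain ", ch)
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chain_roles = chain_roles[chains]),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(x$chain_roles), "chain(s)\n")
  for (ch in names(x$chain_roles)) {
    sel <- x$atoms$chain == ch
    cat(sprintf("  chain %s (%s): %d atoms, %d residues\n", ch,
                x$chain_roles[[ch]], sum(sel),
                length(unique(x$atoms$resid[sel]))))
  }
  invisible(x)
}

# Guess the element from a PDB atom name (columns 13-16). The element is the
# first alphabetic character that is not a leading digit; names starting in
# column 13 with a digit (e.g. "1HB1") are hydrogens.
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm2 <- gsub("[0-9']", "", nm)
    if (nchar(nm2) == 0) stop("cannot infer element from atom name '", nm, "'")
    substr(nm2, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a structure from PDB text
#'
#' Parses a narrow PDB dialect: `ATOM`/`HETATM` records are honored,
#' `TER`/`END` are recognized separators and every other record type is
#' ignored. Alternate locations other than blank or `'A'` are dropped;
#' insertion codes are rejected with an error. Chains are returned in file
#' order.
#'
#' @param pdb either a path to a PDB file or a character vector of PDB lines.
#' @param chain_roles optional named character vector of chain roles passed to
#'   [structure_model()].
#' @return A [structure_model()].
#' @export
read_structure <- function(pdb, chain_roles = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0) stop("empty PDB input")
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (length(idx) == 0) stop("no atoms: PDB input contains no ATOM/HETATM records")
  fw <- function(l, a, b) substr(l, a, b)
  parse_num <- function(txt, lineno, field) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("parse error at line %d: malformed %s field '%s'",
                   lineno[bad[1]], field, txt[bad[1]]))
    }
    v
  }
  l <- lines[idx]
  altloc <- fw(l, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  l <- l[keep]; lineno <- idx[keep]
  if (length(l) == 0) stop("no atoms after alternate-location filtering")
  icode <- trimws(fw(l, 27, 27))
  if (any(icode != "")) {
    stop("insertion codes are not supported (line ",
         lineno[which(icode != "")[1]], ")")
  }
  atoms <- data.frame(
    id = as.integer(parse_num(trimws(fw(l, 7, 11)), lineno, "serial")),
    name = trimws(fw(l, 13, 16)),
    resname = trimws(fw(l, 18, 20)),
    chain = fw(l, 22, 22),
    resid = as.integer(parse_num(trimws(fw(l, 23, 26)), lineno, "residue number")),
    x = parse_num(trimws(fw(l, 31, 38)), lineno, "x coordinate"),
    y = parse_num(trimws(fw(l, 39, 46)), lineno, "y coordinate"),
    z = parse_num(trimws(fw(l, 47, 54)), lineno, "z coordinate"),
    stringsAsFactors = FALSE)
  elem <- trimws(fw(l, 77, 78))
  atoms$element <- ifelse(elem == "", guess_element(atoms$name), elem)
  atoms <- atoms[, c("id", "name", "element", "resname", "resid", "chain",
                     "x", "y", "z")]
  structure_model(atoms, chain_roles)
}

#' Write a structure as PDB text
#'
#' Inverse of [read_structure()] for the supported dialect; coordinates are
#' written with three decimals (PDB fixed width).
#'
#' @param model a [structure_model()].
#' @param file optional path; when `NULL` the PDB lines are returned.
#' @return Invisibly (or visibly when `file` is `NULL`) the character vector
#'   of PDB lines.
#' @export
write_structure <- function(model, file = NULL) {
  a <- model$atoms
  name_fmt <- ifelse(nchar(a$name) <= 3, sprintf(" %-3s", a$name),
                     sprintf("%-4s", a$name))
  lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   a$id %% 100000L, name_fmt, a$resname, a$chain, a$resid,
                   a$x, a$y, a$z, a$element)
  # TER after each chain, END at the end
  out <- character(0)
  for (ch in names(model$chain_roles)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  out <- c(out, "END")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Count atoms of a capped peptide from residue templates
#'
#' Sums per-residue template atom counts (hydrogens included) over a
#' one-letter sequence plus two capping groups. With the bundled Amber-style
#' templates, the capped BH3 18-mer `Ace-IWIAQELRRIGDEFNAYY-Nhe` totals 319
#' atoms.
#'
#' @param sequence one-letter amino-acid string (may be empty only if caps
#'   alone are desired; an empty sequence is rejected).
#' @param n_cap,c_cap three-letter codes of the N- and C-terminal caps.
#' @param table named count vector, by default [residue_template_table()].
#' @return Integer atom count.
#' @export
count_atoms <- function(sequence, n_cap = "ACE", c_cap = "NHE",
                        table = residue_template_table()) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a non-empty one-letter string")
  }
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  codes3 <- AA_CODE_1TO3[letters1]
  if (anyNA(codes3)) {
    stop("unknown residue code: ", letters1[which(is.na(codes3))[1]])
  }
  for (code in c(codes3, n_cap, c_cap)) {
    if (!code %in% names(table)) stop("unknown residue code: ", code)
  }
  as.integer(sum(table[codes3]) + table[[n_cap]] + table[[c_cap]])
}

#' Snapshot bookkeeping for a sampling campaign
#'
#' Number of saved snapshots for `n_traj` trajectories of length
#' `traj_length` saved every `save_interval` (both in the same time unit).
#' The length must divide exactly; no silent rounding.
#'
#' @param n_traj number of parallel trajectories.
#' @param traj_length length of one trajectory.
#' @param save_interval interval between saved frames.
#' @return Total snapshot count (numeric, to allow counts above
#'   `.Machine$integer.max`).
#' @examples
#' plan_snapshots(30, 1e6, 5)  # 30 x 1 us saved every 5 ps -> 6e6
#' @export
plan_snapshots <- function(n_traj, traj_length, save_interval) {
  if (any(c(n_traj, traj_length, save_interval) <= 0)) {
    stop("all inputs must be positive")
  }
  ratio <- traj_length / save_interval
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("traj_length is not an integer multiple of save_interval")
  }
  n_traj * round(ratio)
}
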