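#' Contact set of a structure
#'
#' Heavy-atom pairs within a distance cutoff. Scope `"inter"` keeps only
#' pairs spanning a receptor and a ligand chain; `"intra"` keeps within-chain
#' pairs excluding same-residue pairs and sequence neighbors
#' (`|delta resid| <= 2`); `"both"` is their union. The contact definition
#' (heavy atoms, 4.5 Angstrom default cutoff, atom-pair level) is the
#' package's documented, configurable choice.
#'
#' @param model a [structure_model()].
#' @param scope `"inter"`, `"intra"` or `"both"`.
#' @param cutoff contact cutoff in Angstrom.
#' @return An object of class `contact_set`: a character vector of
#'   `"i-j"` atom-pair keys with attributes `scope` and `cutoff`.
#' @export
contact_set <- function(model, scope = c("inter", "intra", "both"),
                        cutoff = 4.5) {
  scope <- match.arg(scope)
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- model$atoms
  heavy <- which(toupper(a$element) != "H")
  if (length(heavy) < 2) stop("structure has fewer than two heavy atoms")
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  within <- d <= cutoff
  within[lower.tri(within, diag = TRUE)] <- FALSE
  idx <- which(within, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(structure(character(0), scope = scope, cutoff = cutoff,
                     class = "contact_set"))
  }
  i <- heavy[idx[, 1]]; j <- heavy[idx[, 2]]
  roles <- model$chain_roles
  inter <- roles[a$chain[i]] != roles[a$chain[j]]
  intra <- a$chain[i] == a$chain[j] & abs(a$resid[i] - a$resid[j]) > 2
  keep <- switch(scope, inter = inter, intra = intra, both = inter | intra)
  structure(sprintf("%d-%d", i[keep], j[keep]), scope = scope,
            cutoff = cutoff, class = "contact_set")
}

#' Contact-preservation similarity (R-value)
#'
#' Fraction of the reference structure's contacts (in the given scope) that
#' are preserved in the query structure:
#' `R = |C(query) intersect C(reference)| / |C(reference)|`, in `[0, 1]`.
#' A structure against itself scores exactly 1. The measure is asymmetric:
#' swapping query and reference changes the denominator.
#'
#' @param model query [structure_model()] (same topology as the reference).
#' @param reference reference [structure_model()].
#' @param scope,cutoff passed to [contact_set()].
#' @return R-value in `[0, 1]`.
#' @export
r_value <- function(model, reference, scope = "inter", cutoff = 4.5) {
  cref <- contact_set(reference, scope, cutoff)
  if (length(cref) == 0) {
    stop("reference has no contacts in scope '", scope,
         "'; R-value is undefined")
  }
  cq <- contact_set(model, scope, cutoff)
  length(intersect(as.character(cq), as.character(cref))) / length(cref)
}

#' Per-residue R-value decomposition
#'
#' Residue `i`'s value is the preserved fraction of reference contacts that
#' involve at least one atom of residue `i`. Residues without reference
#' contacts in scope are `NA` (undefined). The contact-weighted mean of the
#' per-residue values (each contact counted once per involved residue)
#' equals the global R-value when contacts are intermolecular (each contact
#' belongs to exactly one residue of the analyzed chain).
#'
#' @inheritParams r_value
#' @param chain optional chain id restricting which residues are reported
#'   (default: ligand chains).
#' @return An object of class `rvalue_report`: data frame with `chain`,
#'   `resid`, `n_ref_contacts`, `r` plus attributes `global`, `scope`,
#'   `cutoff`.
#' @export
per_residue_r_value <- function(model, reference, scope = "inter",
                                cutoff = 4.5, chain = NULL) {
  cref <- contact_set(reference, scope, cutoff)
  if (length(cref) == 0) stop("reference has no contacts in scope")
  cq <- as.character(contact_set(model, scope, cutoff))
  preserved <- as.character(cref) %in% cq
  a <- reference$atoms
  ij <- do.call(rbind, strsplit(as.character(cref), "-"))
  ij <- matrix(as.integer(ij), ncol = 2)
  if (is.null(chain)) {
    chain <- names(reference$chain_roles)[reference$chain_roles == "ligand"]
    if (length(chain) == 0) chain <- names(reference$chain_roles)
  }
  rows <- which(a$chain %in% chain)
  res_tab <- unique(a[rows, c("chain", "resid")])
  res_tab$n_ref_contacts <- 0L
  res_tab$r <- NA_real_
  akey <- function(i) paste(a$chain[i], a$resid[i])
  rkey <- paste(res_tab$chain, res_tab$resid)
  for (rr in seq_len(nrow(res_tab))) {
    involved <- akey(ij[, 1]) == rkey[rr] | akey(ij[, 2]) == rkey[rr]
    res_tab$n_ref_contacts[rr] <- sum(involved)
    if (any(involved)) res_tab$r[rr] <- mean(preserved[involved])
  }
  structure(res_tab, global = mean(preserved), scope = scope,
            cutoff = cutoff, class = c("rvalue_report", "data.frame"))
}

# Kabsch optimal rotation (proper) such that P %*% R best matches Q;
# both inputs centered n x 3. With H = t(P) Q = U S V^T the maximizer of
# tr(t(R) H) over rotations is R = U D V^T, D correcting improper flips.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Root-mean-square deviation between structures
#'
#' RMSD over a shared atom selection, optionally after least-squares rigid
#' superposition (Kabsch). `fit_selection` supports the receptor-frame
#' convention for ligand RMSD: superpose on the receptor atoms, then measure
#' the deviation over `selection` (e.g. ligand heavy atoms) without further
#' fitting.
#'
#' @param model,reference structures with matching selections.
#' @param selection atom indices measured (default: all heavy atoms).
#' @param superpose superpose before measuring?
#' @param fit_selection atom indices used for the superposition (defaults to
#'   `selection`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(model, reference, selection = NULL, superpose = TRUE,
                 fit_selection = NULL) {
  heavy <- function(m) which(toupper(m$atoms$element) != "H")
  if (is.null(selection)) selection <- intersect(heavy(model), heavy(reference))
  xyz <- function(m, idx) as.matrix(m$atoms[idx, c("x", "y", "z")])
  if (length(selection) == 0) stop("empty selection")
  P <- xyz(model, selection); Q <- xyz(reference, selection)
  if (nrow(P) != nrow(Q)) stop("mismatched selections")
  if (superpose) {
    fit <- if (is.null(fit_selection)) selection else fit_selection
    Pf <- xyz(model, fit); Qf <- xyz(reference, fit)
    cp <- colMeans(Pf); cq <- colMeans(Qf)
    U <- kabsch_rotation(sweep(Pf, 2, cp), sweep(Qf, 2, cq))
    P <- sweep(P, 2, cp) %*% U
    Q <- sweep(Q, 2, cq)
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Ligand RMSD in the receptor-fixed frame
#'
#' Superposes on receptor heavy atoms, then reports the ligand heavy-atom
#' RMSD — the complex-frame peptide RMSD used to characterize binding
#' configurations.
#'
#' @param model,reference complex structures sharing a topology.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, reference) {
  rec <- select_atoms(reference, role = "receptor")
  lig <- select_atoms(reference, role = "ligand")
  heavy <- which(toupper(reference$atoms$element) != "H")
  rmsd(model, reference, selection = intersect(lig, heavy),
       superpose = TRUE, fit_selection = intersect(rec, heavy))
}
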