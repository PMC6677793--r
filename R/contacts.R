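.hydrophobic_resid <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
.tyr_ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
.backbone_atoms <- c("N", "CA", "C", "O")

#' Ligand-protein contact map
#'
#' Reports every protein residue with a heavy atom within `cutoff` of a
#' ligand heavy atom, one row per (ligand atom, residue) pair with the
#' minimum heavy-atom distance. A contact is classed hydrophobic when the
#' closest protein atom is a carbon/sulfur side-chain atom of a hydrophobic
#' residue (Ala, Val, Leu, Ile, Met, Phe, Trp, Pro, or the Tyr ring);
#' otherwise polar. Hydrogens are ignored throughout.
#'
#' @param x a [cc_structure()] containing HETATM ligand records.
#' @param ligand_resid residue name(s) selecting the ligand among HETATM
#'   records; default all non-water HETATMs.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.0).
#' @param model frame index.
#' @return data.frame with columns `ligand_atom`, `chain`, `resno`, `resid`,
#'   `distance`, `class`.
#' @export
contact_map <- function(x, ligand_resid = NULL, cutoff = 4.0, model = 1) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  atom <- x$atom
  co <- model_coords(x, model)
  lig <- atom$type == "HETATM" & !(atom$resid %in% c("HOH", "WAT")) &
    atom$elesy != "H"
  if (!is.null(ligand_resid)) lig <- lig & atom$resid %in% ligand_resid
  if (!any(lig)) stop("selection error: no ligand heavy atoms found",
                      call. = FALSE)
  prot <- atom$type == "ATOM" & atom$elesy != "H"
  li <- which(lig); pi_ <- which(prot)

  rows <- list()
  for (i in li) {
    d <- sqrt(rowSums(sweep(co[pi_, , drop = FALSE], 2, co[i, ])^2))
    near <- which(d <= cutoff)
    if (!length(near)) next
    key <- paste(atom$chain[pi_[near]], atom$resno[pi_[near]])
    for (k in unique(key)) {
      sub <- near[key == k]
      j <- sub[which.min(d[sub])]
      pj <- pi_[j]
      is_side <- !(atom$elety[pj] %in% .backbone_atoms)
      hydrophobic <- atom$elesy[pj] %in% c("C", "S") && is_side &&
        (atom$resid[pj] %in% .hydrophobic_resid ||
           (atom$resid[pj] == "TYR" && atom$elety[pj] %in% .tyr_ring))
      rows[[length(rows) + 1]] <- data.frame(
        ligand_atom = atom$elety[i], chain = atom$chain[pj],
        resno = atom$resno[pj], resid = atom$resid[pj],
        distance = min(d[sub]),
        class = if (hydrophobic) "hydrophobic" else "polar")
    }
  }
  if (!length(rows))
    return(data.frame(ligand_atom = character(0), chain = character(0),
                      resno = integer(0), resid = character(0),
                      distance = numeric(0), class = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$ligand_atom, out$chain, out$resno), ]
}
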