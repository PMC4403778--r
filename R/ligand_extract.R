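# Ligand identification: group hetero atoms into residues, drop water/solvent,
# apply the strict heavy-atom threshold.

#' Count heavy (non-hydrogen, non-deuterium) atoms
#'
#' Atoms whose element symbol is not recognized are counted as heavy with a
#' warning, never silently dropped.
#'
#' @param atoms atom data.frame with an `element` column.
#' @return integer count.
#' @export
heavy_atom_count <- function(atoms) {
  if (is.null(atoms) || nrow(atoms) == 0L) return(0L)
  el <- toupper(atoms$element)
  unknown <- !(el %in% c(names(COVALENT_RADII), "H", "D"))
  if (any(unknown)) {
    warning(sprintf("unrecognized element symbol(s) counted as heavy: %s",
                    paste(unique(el[unknown]), collapse = ", ")))
  }
  sum(!(el %in% c("H", "D")))
}

#' Identify ligand instances in a structure
#'
#' One instance per hetero residue whose chemical component id is not excluded
#' and whose heavy-atom count is strictly greater than `min_heavy_atoms`
#' (default 8, the solvent guard). Water (HOH/DOD/WAT) is always excluded
#' regardless of `exclusion_list`. Output order is deterministic:
#' (chain, residue number, insertion code).
#'
#' @param s `mtld_structure`.
#' @param min_heavy_atoms strict lower bound on heavy atoms (default 8).
#' @param exclusion_list extra component codes to drop (default none beyond
#'   water).
#' @return list of `ligand_instance` objects with fields `component_id`,
#'   `chain_id`, `residue_seq`, `insertion_code`, `atoms`,
#'   `heavy_atom_count`, `source_structure_id`.
#' @export
identify_ligand_instances <- function(s, min_heavy_atoms = 8L,
                                      exclusion_list = character(0)) {
  het <- s$atoms[s$atoms$record == "hetero", , drop = FALSE]
  excl <- unique(c(WATER_NAMES, toupper(exclusion_list)))
  het <- het[!(het$resname %in% excl), , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  key <- paste(het$chain, het$resseq, het$icode, het$resname, sep = "\r")
  groups <- split(seq_len(nrow(het)), key)
  instances <- lapply(groups, function(idx) {
    atoms <- het[idx, , drop = FALSE]
    rownames(atoms) <- NULL
    structure(
      list(component_id = atoms$resname[1],
           chain_id = atoms$chain[1],
           residue_seq = atoms$resseq[1],
           insertion_code = atoms$icode[1],
           atoms = atoms,
           heavy_atom_count = heavy_atom_count(atoms),
           source_structure_id = s$structure_id),
      class = "ligand_instance")
  })
  instances <- Filter(function(li) li$heavy_atom_count > min_heavy_atoms,
                      instances)
  ord <- order(vapply(instances, function(li) li$chain_id, character(1)),
               vapply(instances, function(li) li$residue_seq, integer(1)),
               vapply(instances, function(li) li$insertion_code, character(1)),
               method = "radix")
  unname(instances[ord])
}

#' Canonical file name for a ligand instance
#' @param li `ligand_instance`.
#' @return `"<structure_id>_<component_id>_<chain>_<residue_seq>.pdb"`
#' @export
ligand_instance_filename <- function(li) {
  sprintf("%s_%s_%s_%d.pdb", li$source_structure_id, li$component_id,
          li$chain_id, li$residue_seq)
}

#' @export
print.ligand_instance <- function(x, ...) {
  cat(sprintf("<ligand_instance %s %s/%s/%d%s in %s> %d atoms (%d heavy)\n",
              x$component_id, x$chain_id, x$component_id, x$residue_seq,
              x$insertion_code, x$source_structure_id, nrow(x$atoms),
              x$heavy_atom_count))
  invisible(x)
}
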