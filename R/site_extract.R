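# Binding-site extraction: all protein residues with any atom within the
# cutoff radius of any ligand atom (inclusive), whole-residue membership.

# residue names treated as protein when deciding site membership
PROTEIN_RESNAMES <- c(names(AA3TO1), "MSE")

#' Extract the binding site of a ligand instance
#'
#' The site is the set of amino-acid polymer residues having any atom at
#' Euclidean distance `<= radius` from any ligand atom (hydrogens of the
#' ligand participate when present). Member residues contribute all of their
#' atoms (whole-residue inclusion); the ligand's own atoms and other hetero
#' groups are never site members. An empty site (no residue in range) is
#' returned as a site with zero residues, not an error.
#'
#' @param s `mtld_structure` the ligand belongs to.
#' @param lig `ligand_instance`.
#' @param radius cutoff in Angstrom (default 6.0), inclusive.
#' @return `binding_site`: `ligand_ref` (structure, component, chain,
#'   residue number), `residues` (data.frame chain/resseq/icode/resname/
#'   min_dist ordered by chain, resseq, icode), `residue_count`,
#'   `contributing_chain_tally` (named integer vector) and `site_atoms`.
#' @export
extract_binding_site <- function(s, lig, radius = 6.0) {
  stopifnot(radius > 0)
  prot <- s$atoms[s$atoms$record == "polymer" &
                    s$atoms$resname %in% PROTEIN_RESNAMES, , drop = FALSE]
  lig_xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  ligand_ref <- list(structure_id = lig$source_structure_id,
                     component_id = lig$component_id,
                     chain = lig$chain_id,
                     residue_seq = lig$residue_seq)

  empty_site <- function() {
    structure(list(ligand_ref = ligand_ref,
                   residues = data.frame(chain = character(0),
                                         resseq = integer(0),
                                         icode = character(0),
                                         resname = character(0),
                                         min_dist = numeric(0),
                                         stringsAsFactors = FALSE),
                   residue_count = 0L,
                   contributing_chain_tally = integer(0),
                   site_atoms = empty_atom_table()),
              class = "binding_site")
  }
  if (nrow(prot) == 0L) return(empty_site())

  # min distance from each protein atom to any ligand atom
  px <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rep(1, nrow(lig_xyz))) +
    outer(rep(1, nrow(px)), rowSums(lig_xyz^2)) -
    2 * px %*% t(lig_xyz)
  d2[d2 < 0] <- 0
  atom_min <- sqrt(apply(d2, 1, min))

  key <- paste(prot$chain, prot$resseq, prot$icode, sep = "\r")
  res_min <- tapply(atom_min, key, min)
  member_keys <- names(res_min)[res_min <= radius]
  if (length(member_keys) == 0L) return(empty_site())

  in_site <- key %in% member_keys
  site_atoms <- prot[in_site, , drop = FALSE]
  rownames(site_atoms) <- NULL

  first <- !duplicated(key) & in_site
  residues <- prot[first, c("chain", "resseq", "icode", "resname")]
  residues$min_dist <- as.numeric(res_min[key[first]])
  ord <- order(residues$chain, residues$resseq, residues$icode,
               method = "radix")
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL

  tally <- table(residues$chain)
  tally <- stats::setNames(as.integer(tally),
                           names(tally))[sort(names(tally), method = "radix")]

  structure(list(ligand_ref = ligand_ref,
                 residues = residues,
                 residue_count = nrow(residues),
                 contributing_chain_tally = tally,
                 site_atoms = site_atoms),
            class = "binding_site")
}

#' Site-size gate
#'
#' True iff the site has strictly more than `min_residues` residues
#' (default 5).
#'
#' @param site `binding_site`.
#' @param min_residues strict lower bound (default 5).
#' @return logical scalar.
#' @export
passes_site_filter <- function(site, min_residues = 5L) {
  site$residue_count > min_residues
}

#' Chain contributing the most site residues
#'
#' Ties are broken alphabetically by chain id. The primary chain maps a
#' multi-chain site to one target sequence for redundancy filtration.
#'
#' @param site `binding_site` with at least one residue.
#' @return chain id (character scalar).
#' @export
primary_binding_chain <- function(site) {
  tally <- site$contributing_chain_tally
  if (length(tally) == 0L) stop("empty binding site has no primary chain")
  chains <- sort(names(tally), method = "radix")
  chains[which.max(tally[chains])]
}

#' Write the sidecar TSV of site member residues
#'
#' Columns: chain, resseq, icode, resname, min distance to the ligand in
#' Angstrom (3 decimals).
#'
#' @param site `binding_site`.
#' @param path output path; `NULL` returns the TSV text.
#' @export
write_site_tsv <- function(site, path = NULL) {
  df <- site$residues
  lines <- c("chain\tresseq\ticode\tresname\tmin_dist",
             sprintf("%s\t%d\t%s\t%s\t%.3f", df$chain, df$resseq, df$icode,
                     df$resname, df$min_dist))
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site for %s in %s> %d residues over %d chain(s)\n",
              x$ligand_ref$component_id, x$ligand_ref$structure_id,
              x$residue_count, length(x$contributing_chain_tally)))
  invisible(x)
}
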