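# Legacy PDB text I/O: fixed-column ATOM/HETATM parsing, REMARK 2 resolution,
# EXPDTA method, first-MODEL selection, substructure writing, chain sequences.

#' Three-letter to one-letter amino-acid code table
#'
#' Named character vector mapping the 20 standard residue names to one-letter
#' codes. Unknown residue names map to `"X"` in [chain_sequences()].
#' @keywords internal
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Water residue names always excluded from ligand extraction
#' @keywords internal
WATER_NAMES <- c("HOH", "DOD", "WAT")

empty_atom_table <- function() {
  data.frame(
    record = character(0), serial = integer(0), name = character(0),
    alt_loc = character(0), resname = character(0), chain = character(0),
    resseq = integer(0), icode = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    occupancy = numeric(0), element = character(0),
    stringsAsFactors = FALSE
  )
}

# Two-letter element symbols we recognize when inferring elements from atom
# names (columns 77-78 absent in many older files).
TWO_LETTER_ELEMENTS <- c(
  "FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "SE", "CU", "NI",
  "CO", "CD", "HG", "PT", "AU", "AG", "AL", "AS", "MO", "LI", "SI"
)

infer_element <- function(name, resname) {
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  if (nchar(nm) == 0L) return("")
  # hydrogens named like 1HB / HB2 / HD11
  if (substr(nm, 1, 1) %in% c("H", "D") &&
      !(nm %in% TWO_LETTER_ELEMENTS)) {
    return(substr(nm, 1, 1))
  }
  if (nchar(nm) >= 2L && substr(nm, 1, 2) %in% TWO_LETTER_ELEMENTS) {
    # heuristic: CA in an amino-acid residue is an alpha carbon, not calcium
    if (substr(nm, 1, 2) %in% c("CA", "CD", "NA") && resname %in% names(AA3TO1)) {
      return(substr(nm, 1, 1))
    }
    return(substr(nm, 1, 2))
  }
  substr(nm, 1, 1)
}

#' Parse a legacy PDB structure from text
#'
#' Reads ATOM/HETATM records with fixed-column semantics, keeping only the
#' first MODEL when several are present. Resolution is taken from the
#' `REMARK   2 RESOLUTION.` record when parseable, the experiment method from
#' `EXPDTA`, and the structure id from `HEADER` columns 63-66 (falling back to
#' `structure_id`). Alternate locations other than blank or `"A"` are dropped.
#' Elements come from columns 77-78, or are inferred from the atom name when
#' those columns are empty. Malformed coordinate lines are skipped with a
#' warning; a file without any coordinate line is an error.
#'
#' @param pdb_text character scalar (possibly multi-line) or character vector
#'   of lines.
#' @param structure_id fallback 4-character identifier when no HEADER record
#'   carries one.
#' @return An object of class `mtld_structure`: a list with `structure_id`,
#'   `experiment_method`, `resolution` (Angstrom, `NA` when absent), `atoms`
#'   (a data.frame, one row per atom, file order preserved) and `model_count`.
#' @examples
#' txt <- c(
#'   "ATOM      1  CA  ALA A   1      11.000   2.000   3.000  1.00  0.00           C",
#'   "HETATM    2  C1  LIG X   1       1.000   2.000   3.000  1.00  0.00           C",
#'   "END")
#' s <- parse_structure(txt, structure_id = "TEST")
#' nrow(s$atoms)
#' @export
parse_structure <- function(pdb_text, structure_id = "XXXX") {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(pdb_text)
  }

  rec <- substr(lines, 1, 6)
  model_count <- sum(trimws(rec) == "MODEL")
  if (model_count == 0L) model_count <- 1L

  # restrict to the first model: everything before the first ENDMDL
  first_end <- which(trimws(rec) == "ENDMDL")
  coord_ok <- rep(TRUE, length(lines))
  if (length(first_end) > 0L) coord_ok[seq_along(lines) > first_end[1]] <- FALSE

  resolution <- NA_real_
  res_idx <- grep("^REMARK   2 RESOLUTION\\.", lines)
  if (length(res_idx) > 0L) {
    m <- regmatches(lines[res_idx[1]],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]+ANGSTROM)",
                            lines[res_idx[1]], perl = TRUE))
    if (length(m) == 1L) resolution <- as.numeric(m)
  }

  method <- ""
  exp_idx <- grep("^EXPDTA", lines)
  if (length(exp_idx) > 0L) method <- trimws(substr(lines[exp_idx[1]], 11, 79))

  hdr_idx <- grep("^HEADER", lines)
  if (length(hdr_idx) > 0L) {
    id <- trimws(substr(lines[hdr_idx[1]], 63, 66))
    if (nchar(id) == 4L) structure_id <- id
  }

  is_atom <- (rec == "ATOM  " | rec == "HETATM") & coord_ok
  atom_lines <- lines[is_atom]
  if (length(atom_lines) == 0L) {
    stop("no ATOM or HETATM records found: empty structure")
  }

  record <- ifelse(substr(atom_lines, 1, 6) == "ATOM  ", "polymer", "hetero")
  serial <- suppressWarnings(as.integer(substr(atom_lines, 7, 11)))
  name <- trimws(substr(atom_lines, 13, 16))
  alt_loc <- trimws(substr(atom_lines, 17, 17))
  resname <- trimws(substr(atom_lines, 18, 20))
  chain <- substr(atom_lines, 22, 22)
  resseq <- suppressWarnings(as.integer(substr(atom_lines, 23, 26)))
  icode <- trimws(substr(atom_lines, 27, 27))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 47, 54)))
  occupancy <- suppressWarnings(as.numeric(substr(atom_lines, 55, 60)))
  occupancy[is.na(occupancy)] <- 1.0
  element <- trimws(substr(atom_lines, 77, 78))

  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resseq) | nchar(name) == 0L
  if (any(bad)) {
    warning(sprintf("skipped %d malformed coordinate line(s) in %s",
                    sum(bad), structure_id))
  }
  keep <- !bad & (alt_loc == "" | alt_loc == "A")

  atoms <- data.frame(
    record = record[keep], serial = serial[keep], name = name[keep],
    alt_loc = alt_loc[keep], resname = resname[keep], chain = chain[keep],
    resseq = resseq[keep], icode = icode[keep],
    x = x[keep], y = y[keep], z = z[keep],
    occupancy = occupancy[keep], element = toupper(element[keep]),
    stringsAsFactors = FALSE
  )
  if (nrow(atoms) == 0L) stop("no valid coordinate lines after filtering")

  missing_el <- atoms$element == ""
  if (any(missing_el)) {
    atoms$element[missing_el] <- mapply(
      infer_element, atoms$name[missing_el], atoms$resname[missing_el],
      USE.NAMES = FALSE)
  }
  rownames(atoms) <- NULL

  structure(
    list(structure_id = structure_id, experiment_method = method,
         resolution = resolution, atoms = atoms, model_count = model_count),
    class = "mtld_structure"
  )
}

#' Read and parse a PDB file from disk
#' @param path file path to a legacy PDB text file.
#' @return see [parse_structure()].
#' @export
read_structure <- function(path) {
  id <- toupper(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))
  if (nchar(id) != 4L) id <- substr(paste0(id, "XXXX"), 1, 4)
  parse_structure(readLines(path, warn = FALSE), structure_id = id)
}

#' @export
print.mtld_structure <- function(x, ...) {
  cat(sprintf("<mtld_structure %s> %d atoms, %d model(s), method='%s', resolution=%s\n",
              x$structure_id, nrow(x$atoms), x$model_count, x$experiment_method,
              ifelse(is.na(x$resolution), "absent", format(x$resolution))))
  invisible(x)
}

#' Structure-level quality gate
#'
#' A structure passes iff its experiment method indicates X-ray diffraction
#' (when `require_xray` is on) and its resolution is present and strictly
#' below `max_resolution`. A structure with no parseable resolution never
#' passes: resolution is not guessed.
#'
#' @param s `mtld_structure`.
#' @param max_resolution Angstrom bound, exclusive (default 3.0).
#' @param require_xray require an X-ray method string (default TRUE).
#' @return logical scalar.
#' @export
passes_structure_filter <- function(s, max_resolution = 3.0, require_xray = TRUE) {
  if (require_xray && !grepl("X-RAY", toupper(s$experiment_method), fixed = TRUE)) {
    return(FALSE)
  }
  !is.na(s$resolution) && s$resolution < max_resolution
}

#' Per-chain protein sequences from ATOM records
#'
#' Builds one sequence per chain having at least one polymer residue, walking
#' residues in file order and collapsing duplicate
#' (chain, residue number, insertion code) keys to their first occurrence.
#' Three-letter codes outside the standard 20 map to `"X"` unless the opt-in
#' `mse_to_met` maps selenomethionine to M.
#'
#' @param s `mtld_structure`.
#' @param mse_to_met map MSE to M (default FALSE).
#' @return list of `chain_sequence` objects: `chain_id`, `sequence`
#'   (one-letter text) and `residue_index_map` (data.frame of `resseq`,
#'   `icode` aligned to sequence positions).
#' @export
chain_sequences <- function(s, mse_to_met = FALSE) {
  tbl <- AA3TO1
  if (mse_to_met) tbl <- c(tbl, MSE = "M")
  atoms <- s$atoms[s$atoms$record == "polymer", , drop = FALSE]
  if (nrow(atoms) == 0L) return(list())
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  first <- !duplicated(key)
  res <- atoms[first, c("chain", "resseq", "icode", "resname")]
  out <- list()
  for (ch in sort(unique(res$chain), method = "radix")) {
    sub <- res[res$chain == ch, , drop = FALSE]
    letters1 <- unname(tbl[sub$resname])
    letters1[is.na(letters1)] <- "X"
    out[[ch]] <- structure(
      list(chain_id = ch,
           sequence = paste(letters1, collapse = ""),
           residue_index_map = data.frame(resseq = sub$resseq,
                                          icode = sub$icode,
                                          stringsAsFactors = FALSE)),
      class = "chain_sequence")
  }
  out
}

format_pdb_atom_line <- function(record, serial, name, alt_loc, resname,
                                 chain, resseq, icode, x, y, z, occupancy,
                                 element) {
  # PDB convention: atom names of <4 chars start in column 14
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(record == "polymer", "ATOM", "HETATM"),
          serial %% 100000L, nm,
          substr(paste0(alt_loc, " "), 1, 1), resname, chain, resseq %% 10000L,
          substr(paste0(icode, " "), 1, 1), x, y, z, occupancy, 0, element)
}

#' Write an atom subset as standalone PDB text
#'
#' Output re-parses to atoms equal in name, residue, chain and coordinates
#' (to the PDB's 3-decimal precision), and ends with an END record. Writing
#' is deterministic: the same atoms always produce identical bytes.
#'
#' @param atoms atom data.frame (as held by `mtld_structure$atoms`).
#' @param header_comment optional text placed in a leading REMARK record.
#' @return character scalar of PDB text.
#' @export
write_substructure <- function(atoms, header_comment = "") {
  if (is.null(atoms) || nrow(atoms) == 0L) stop("empty atom list")
  lines <- character(0)
  if (nzchar(header_comment)) {
    lines <- sprintf("REMARK 999 %s", header_comment)
  }
  body <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    format_pdb_atom_line(a$record, a$serial, a$name, a$alt_loc, a$resname,
                         a$chain, a$resseq, a$icode, a$x, a$y, a$z,
                         a$occupancy, a$element)
  }, character(1))
  paste(c(lines, body, "END"), collapse = "\n")
}

#' Write chain sequences as FASTA
#'
#' One record per chain, identifier `<structure_id>_<chain_id>`.
#'
#' @param seqs list of `chain_sequence` (see [chain_sequences()]).
#' @param structure_id 4-character structure code used in record ids.
#' @param path output file; when `NULL` the FASTA text is returned instead.
#' @export
write_chain_fasta <- function(seqs, structure_id, path = NULL) {
  txt <- unlist(lapply(seqs, function(cs) {
    c(sprintf(">%s_%s", structure_id, cs$chain_id), cs$sequence)
  }))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}
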