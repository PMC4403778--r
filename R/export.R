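# Database export: per-record directories with ligand/site PDB files,
# SMILES, FASTA and record JSON; corpus-level TSVs; a hashed manifest.

record_json_view <- function(rec) {
  list(
    component_id = rec$component_id,
    complexes = lapply(rec$instances, function(li) {
      list(structure_id = li$source_structure_id, chain = li$chain_id,
           residue_seq = li$residue_seq,
           heavy_atom_count = li$heavy_atom_count)
    }),
    target_clusters = lapply(rec$target_clusters, function(cl) {
      list(members = as.list(cl$members), representative = cl$representative)
    }),
    nonredundant_target_count = rec$nonredundant_target_count,
    is_mtl = rec$is_mtl,
    descriptors = list(
      molecular_weight = rec$descriptors$molecular_weight,
      hbd = rec$descriptors$hbd, hba = rec$descriptors$hba,
      logp = rec$descriptors$logp,
      lipinski_violations = rec$descriptors$lipinski_violations,
      druglike = rec$descriptors$druglike),
    smiles = rec$smiles,
    fingerprint = list(bits = as.list(rec$fingerprint$bits),
                       n_bits = rec$fingerprint$n_bits,
                       max_path_len = rec$fingerprint$max_path_len,
                       hash_version = rec$fingerprint$hash_version),
    conformer = if (is.null(rec$conformer_report)) NULL else list(
      n_conformers = length(rec$conformer_report$conformer_keys),
      max_rmsd = rec$conformer_report$max_rmsd,
      flexibility_class = rec$conformer_report$flexibility_class),
    annotations = rec$annotations)
}

#' Read back an exported record JSON
#'
#' Returns the same serializable view written by [export_database()], so
#' export followed by re-import round-trips exactly.
#' @param path a `record.json` file.
#' @return named list (record view).
#' @export
read_record_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Export a database to a directory tree
#'
#' Each record directory carries the five information classes: ligand
#' conformer PDB files, binding-site PDB files (with residue TSV sidecars),
#' the SMILES string, a FASTA of target-representative sequences, and the
#' record JSON. Corpus-level files: records.tsv, stats.json, clusters.tsv,
#' config.json, stage_counts.tsv, and manifest.tsv listing every written
#' file with its md5 hash. Re-running on the same database reproduces
#' identical bytes.
#'
#' @param db `mtld_database`.
#' @param out_dir output directory (created; must be creatable/writable).
#' @return data.frame manifest (path, md5), invisibly written to
#'   `manifest.tsv`.
#' @export
export_database <- function(db, out_dir) {
  parent <- dirname(out_dir)
  if (!dir.exists(parent) || file.access(parent, 2L) != 0L) {
    stop("output location not writable: ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec_root <- file.path(out_dir, "records")
  dir.create(rec_root, showWarnings = FALSE)

  written <- character(0)
  put <- function(path, text) {
    con <- file(path, open = "wb")  # fixed newlines across platforms
    writeLines(text, con, sep = "\n")
    close(con)
    written <<- c(written, path)
  }

  for (comp in sort(names(db$records), method = "radix")) {
    rec <- db$records[[comp]]
    rdir <- file.path(rec_root, comp)
    dir.create(rdir, showWarnings = FALSE)
    for (li in rec$instances) {
      put(file.path(rdir, ligand_instance_filename(li)),
          write_substructure(li$atoms,
                             header_comment = sprintf("LIGAND %s", comp)))
    }
    for (site in rec$sites) {
      base <- sprintf("site_%s_%s_%d", site$ligand_ref$structure_id,
                      site$ligand_ref$chain, site$ligand_ref$residue_seq)
      if (nrow(site$site_atoms) > 0L) {
        put(file.path(rdir, paste0(base, ".pdb")),
            write_substructure(site$site_atoms,
                               header_comment = sprintf("SITE %s", comp)))
      }
      put(file.path(rdir, paste0(base, ".tsv")), write_site_tsv(site))
    }
    put(file.path(rdir, "smiles.txt"),
        sprintf("%s\t%s", comp, rec$smiles))
    reps <- vapply(rec$target_clusters, `[[`, character(1), "representative")
    fasta <- unlist(lapply(reps, function(k) {
      c(paste0(">", k), rec$chain_table$sequence[rec$chain_table$key == k])
    }))
    put(file.path(rdir, "targets.fasta"), fasta)
    put(file.path(rdir, "record.json"),
        jsonlite::toJSON(record_json_view(rec), auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE))
  }

  recs <- db$records[sort(names(db$records), method = "radix")]
  put(file.path(out_dir, "records.tsv"), c(
    paste("component_id", "n_instances", "n_sites", "n_targets", "is_mtl",
          "molecular_weight", "druglike", "max_rmsd", "flexibility_class",
          "smiles", sep = "\t"),
    vapply(recs, function(r) {
      cr <- r$conformer_report
      sprintf("%s\t%d\t%d\t%d\t%s\t%.3f\t%s\t%s\t%s\t%s",
              r$component_id, length(r$instances), length(r$sites),
              r$nonredundant_target_count,
              ifelse(r$is_mtl, "TRUE", "FALSE"),
              r$descriptors$molecular_weight,
              ifelse(r$descriptors$druglike, "TRUE", "FALSE"),
              if (is.null(cr) || is.na(cr$max_rmsd)) "NA"
              else sprintf("%.3f", cr$max_rmsd),
              if (is.null(cr)) "NA" else cr$flexibility_class,
              r$smiles)
    }, character(1))))

  cluster_rows <- unlist(lapply(recs, function(r) {
    unlist(lapply(seq_along(r$target_clusters), function(i) {
      sprintf("%s\t%d\t%s", r$component_id, i,
              r$target_clusters[[i]]$members)
    }))
  }))
  put(file.path(out_dir, "clusters.tsv"),
      c("component_id\tcluster_id\tchain_key", cluster_rows))

  put(file.path(out_dir, "stats.json"),
      jsonlite::toJSON(list(
        target_count_bins = as.list(db$stats$target_count_bins),
        mw_histogram = as.list(db$stats$mw_histogram),
        rmsd_histogram = as.list(db$stats$rmsd_histogram),
        rigid_fraction = db$stats$rigid_fraction,
        druglike_fraction = db$stats$druglike_fraction,
        annotation_fractions = as.list(db$stats$annotation_fractions),
        structure_count = db$structure_count,
        site_count = db$site_count),
        auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE))

  put(file.path(out_dir, "config.json"),
      jsonlite::toJSON(unclass(db$config), auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE))

  put(file.path(out_dir, "stage_counts.tsv"), c(
    "stage\tcount",
    sprintf("%s\t%d", names(db$stage_counts), db$stage_counts)))

  rel <- sort(substring(written, nchar(out_dir) + 2L), method = "radix")
  md5 <- unname(tools::md5sum(file.path(out_dir, rel)))
  manifest <- data.frame(path = rel, md5 = md5, stringsAsFactors = FALSE)
  put(file.path(out_dir, "manifest.tsv"),
      c("path\tmd5", sprintf("%s\t%s", manifest$path, manifest$md5)))
  invisible(manifest)
}
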