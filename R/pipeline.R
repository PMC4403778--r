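# Pipeline orchestration: structure filter -> ligand extraction -> site
# extraction/filter -> per-component aggregation -> multi-structure gate ->
# identity filtration -> MTL decision -> conformer analysis -> chemical
# annotation -> statistics -> export.

#' Pipeline configuration
#'
#' Houses every numeric criterion of the mining procedure. Defaults:
#' X-ray structures below 3.0 Angstrom resolution; ligands with strictly
#' more than 8 heavy atoms; binding sites at a 6.0 Angstrom radius with
#' strictly more than 5 residues; 35 percent sequence-identity redundancy
#' threshold (filtration on); 2.0 Angstrom rigid/flexible RMSD cutoff;
#' 0.8 Tanimoto search cutoff.
#'
#' @param max_resolution Angstrom, exclusive bound (default 3.0).
#' @param require_xray require X-ray method (default TRUE).
#' @param min_heavy_atoms strict heavy-atom bound (default 8).
#' @param site_radius site cutoff radius in Angstrom (default 6.0).
#' @param min_site_residues strict site-size bound (default 5).
#' @param identity_threshold percent identity (default 35).
#' @param identity_filtration collapse redundant targets (default TRUE).
#' @param rmsd_class_cutoff rigid/flexible cutoff in Angstrom (default 2.0).
#' @param tanimoto_cutoff similarity-search cutoff (default 0.8).
#' @param random_seed seed recorded for fixture generation only.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(max_resolution = 3.0, require_xray = TRUE,
                            min_heavy_atoms = 8L, site_radius = 6.0,
                            min_site_residues = 5L, identity_threshold = 35,
                            identity_filtration = TRUE,
                            rmsd_class_cutoff = 2.0, tanimoto_cutoff = 0.8,
                            random_seed = NA_integer_) {
  stopifnot(max_resolution > 0, min_heavy_atoms >= 0, site_radius > 0,
            min_site_residues >= 0, identity_threshold > 0,
            identity_threshold <= 100, rmsd_class_cutoff > 0,
            tanimoto_cutoff >= 0, tanimoto_cutoff <= 1)
  structure(
    list(max_resolution = max_resolution, require_xray = require_xray,
         min_heavy_atoms = as.integer(min_heavy_atoms),
         site_radius = site_radius,
         min_site_residues = as.integer(min_site_residues),
         identity_threshold = identity_threshold,
         identity_filtration = identity_filtration,
         rmsd_class_cutoff = rmsd_class_cutoff,
         tanimoto_cutoff = tanimoto_cutoff,
         random_seed = random_seed),
    class = "pipeline_config")
}

#' MTL decision for a ligand record
#'
#' A record is a multiple-target ligand iff its non-redundant target count
#' is at least 2.
#' @param rec ligand record (element of `mtld_database$records`).
#' @return logical scalar.
#' @export
classify_mtl <- function(rec) {
  rec$nonredundant_target_count >= 2L
}

#' Run the full mining pipeline over a directory of PDB files
#'
#' Stages run in order: structure quality gate, ligand extraction, site
#' extraction and site-size gate, per-component aggregation, restriction to
#' components found in at least 2 distinct structures, sequence-identity
#' filtration of the primary binding chains, MTL decision, conformer
#' analysis, chemical annotation, statistics. Deterministic: the same input
#' directory always yields the same database and byte-identical exports.
#' Unreadable files are skipped with a logged warning; zero surviving
#' structures yield an empty database with a stage report, not an error.
#'
#' @param pdb_dir directory of `.pdb` files (one structure per file).
#' @param config `pipeline_config`.
#' @param verbose log per-stage counters to stderr (default FALSE).
#' @return `mtld_database`: `records` (named list, one per retained
#'   component), `structure_count`, `site_count`, `stats`, `config`,
#'   `stage_counts`.
#' @export
run_pipeline <- function(pdb_dir, config = pipeline_config(), verbose = FALSE) {
  files <- sort(list.files(pdb_dir, pattern = "\\.pdb$", full.names = TRUE),
                method = "radix")
  if (length(files) == 0L) stop("no PDB files in ", pdb_dir)
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(fmt, ...))
  }

  structures <- list()
  unreadable <- 0L
  for (f in files) {
    s <- tryCatch(read_structure(f), error = function(e) {
      warning(sprintf("skipping unreadable file %s: %s", basename(f),
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(s)) structures[[s$structure_id]] <- s
  }
  unreadable <- length(files) - length(structures)
  stage <- c(files_seen = length(files), parsed = length(structures))

  keep <- vapply(structures, passes_structure_filter, logical(1),
                 max_resolution = config$max_resolution,
                 require_xray = config$require_xray)
  structures <- structures[keep]
  stage <- c(stage, resolution_filtered = length(structures))
  log_stage("structures passing quality gate: %d", length(structures))

  # ligand + site extraction
  complexes <- list()  # per qualifying (instance, site) pair
  n_instances <- 0L
  for (sid in sort(names(structures), method = "radix")) {
    s <- structures[[sid]]
    seqs <- chain_sequences(s)
    instances <- identify_ligand_instances(
      s, min_heavy_atoms = config$min_heavy_atoms)
    n_instances <- n_instances + length(instances)
    for (li in instances) {
      site <- extract_binding_site(s, li, radius = config$site_radius)
      if (!passes_site_filter(site, config$min_site_residues)) next
      pchain <- primary_binding_chain(site)
      if (is.null(seqs[[pchain]])) next  # site on a non-sequenced chain
      complexes[[length(complexes) + 1L]] <- list(
        structure_id = sid, instance = li, site = site,
        chain_key = sprintf("%s_%s", sid, pchain),
        chain_sequence = seqs[[pchain]]$sequence)
    }
  }
  stage <- c(stage, ligand_instances = n_instances,
             qualifying_sites = length(complexes))
  log_stage("ligand instances: %d; qualifying sites: %d", n_instances,
            length(complexes))

  comp_ids <- vapply(complexes, function(cx) cx$instance$component_id,
                     character(1))
  by_comp <- split(seq_along(complexes), comp_ids)
  stage <- c(stage, unique_components = length(by_comp))

  # multi-structure gate: >= 2 distinct structure ids
  multi <- Filter(function(idx) {
    length(unique(vapply(complexes[idx], `[[`, character(1),
                         "structure_id"))) >= 2L
  }, by_comp)
  stage <- c(stage, multi_structure_components = length(multi))
  log_stage("components in >=2 structures: %d", length(multi))

  records <- list()
  for (comp in sort(names(multi), method = "radix")) {
    idx <- multi[[comp]]
    cplx <- complexes[idx]
    ord <- order(vapply(cplx, `[[`, character(1), "structure_id"),
                 vapply(cplx, function(cx) cx$instance$chain_id, character(1)),
                 vapply(cplx, function(cx) cx$instance$residue_seq, integer(1)),
                 method = "radix")
    cplx <- cplx[ord]

    chain_tbl <- data.frame(
      key = vapply(cplx, `[[`, character(1), "chain_key"),
      sequence = vapply(cplx, `[[`, character(1), "chain_sequence"),
      stringsAsFactors = FALSE)
    chain_tbl <- chain_tbl[!duplicated(chain_tbl$key), , drop = FALSE]
    ident <- identity_matrix(chain_tbl)
    clusters <- cluster_targets(chain_tbl,
                                threshold = config$identity_threshold,
                                identity = ident)
    n_targets <- nonredundant_target_count(
      chain_tbl, threshold = config$identity_threshold,
      filtration_enabled = config$identity_filtration, identity = ident)

    instances <- lapply(cplx, `[[`, "instance")
    conf <- if (length(instances) >= 2L) {
      conformer_report(instances, class_cutoff = config$rmsd_class_cutoff)
    } else {
      NULL
    }

    ref_atoms <- instances[[1]]$atoms
    graph <- perceive_bonds(ref_atoms, component_id = comp)
    rec <- list(
      component_id = comp,
      instances = instances,
      sites = lapply(cplx, `[[`, "site"),
      chain_table = chain_tbl,
      target_clusters = clusters,
      nonredundant_target_count = as.integer(n_targets),
      descriptors = lipinski(graph),
      fingerprint = path_fingerprint(graph),
      smiles = to_smiles(graph),
      conformer_report = conf,
      annotations = list())
    rec$is_mtl <- classify_mtl(rec)
    records[[comp]] <- rec
  }
  stage <- c(stage, mtl_records = sum(vapply(records, `[[`, logical(1),
                                             "is_mtl")))
  log_stage("MTL records: %d of %d candidates", stage[["mtl_records"]],
            length(records))

  db <- structure(
    list(records = records,
         structure_count = length(unique(unlist(lapply(records, function(r) {
           vapply(r$instances, `[[`, character(1), "source_structure_id")
         })))),
         site_count = sum(vapply(records, function(r) length(r$sites),
                                 integer(1))),
         stats = NULL,
         config = config,
         stage_counts = stage),
    class = "mtld_database")
  db$stats <- compute_stats(db)
  db
}

#' Corpus-level statistics bundle
#'
#' Target-count bins over MTL records exactly as reported
#' (2 | 3-5 | 6-10 | >10), a 100-Da molecular-weight histogram, a
#' 0.5-Angstrom max-RMSD histogram with the rigid (<= cutoff) fraction, the
#' drug-like fraction over all records, and per-annotation fractions when
#' external lists were applied.
#'
#' @param db `mtld_database`.
#' @return `stats_bundle` list.
#' @export
compute_stats <- function(db) {
  records <- db$records
  mtl <- Filter(function(r) r$is_mtl, records)
  counts <- vapply(mtl, function(r) as.numeric(r$nonredundant_target_count),
                   numeric(1))
  bins <- c("2" = sum(counts == 2L),
            "3-5" = sum(counts >= 3L & counts <= 5L),
            "6-10" = sum(counts >= 6L & counts <= 10L),
            ">10" = sum(counts > 10L))

  mws <- vapply(records, function(r) r$descriptors$molecular_weight,
                numeric(1))
  mw_hist <- if (length(mws) > 0L) {
    brk <- seq(0, 100 * ceiling(max(mws) / 100), by = 100)
    h <- hist(mws, breaks = brk, plot = FALSE, right = TRUE)
    stats::setNames(h$counts, sprintf("%d-%d", utils::head(brk, -1), brk[-1]))
  } else {
    integer(0)
  }

  rmsds <- unlist(lapply(records, function(r) {
    if (!is.null(r$conformer_report)) r$conformer_report$max_rmsd else NULL
  }))
  rmsds <- rmsds[!is.na(rmsds)]
  rmsd_hist <- if (length(rmsds) > 0L) {
    brk <- seq(0, 0.5 * ceiling(max(c(rmsds, 0.5)) / 0.5), by = 0.5)
    h <- hist(rmsds, breaks = brk, plot = FALSE, right = TRUE)
    stats::setNames(h$counts, sprintf("%.1f-%.1f", utils::head(brk, -1),
                                      brk[-1]))
  } else {
    integer(0)
  }
  cutoff <- db$config$rmsd_class_cutoff
  rigid_fraction <- if (length(rmsds) > 0L) mean(rmsds <= cutoff) else NA_real_

  druglike_fraction <- if (length(records) > 0L) {
    mean(vapply(records, function(r) r$descriptors$druglike, logical(1)))
  } else {
    NA_real_
  }

  ann_names <- unique(unlist(lapply(records, function(r) names(r$annotations))))
  annotation_fractions <- stats::setNames(
    vapply(ann_names, function(nm) {
      mean(vapply(records, function(r) isTRUE(r$annotations[[nm]]),
                  logical(1)))
    }, numeric(1)), ann_names)

  structure(
    list(target_count_bins = bins, mw_histogram = mw_hist,
         rmsd_histogram = rmsd_hist, rigid_fraction = rigid_fraction,
         druglike_fraction = druglike_fraction,
         annotation_fractions = annotation_fractions),
    class = "stats_bundle")
}

#' Flag records against user-supplied component-id lists
#'
#' Replaces live database cross-referencing: each named list of component
#' ids (e.g. approved drugs) becomes a boolean flag on every record, and the
#' stats bundle gains the per-list fraction. Ids naming components absent
#' from the database are counted and logged, not fatal.
#'
#' @param db `mtld_database`.
#' @param id_lists named list: list name -> character vector of component
#'   ids.
#' @return updated `mtld_database`.
#' @export
annotate_external <- function(db, id_lists) {
  if (length(id_lists) == 0L) return(db)
  stopifnot(!is.null(names(id_lists)), all(nzchar(names(id_lists))))
  known <- names(db$records)
  for (nm in names(id_lists)) {
    ids <- toupper(id_lists[[nm]])
    unknown <- setdiff(ids, known)
    if (length(unknown) > 0L) {
      warning(sprintf("annotation list '%s': %d unknown component id(s)",
                      nm, length(unknown)))
    }
    for (comp in known) {
      db$records[[comp]]$annotations[[nm]] <- comp %in% ids
    }
  }
  db$stats <- compute_stats(db)
  db
}

#' @export
print.mtld_database <- function(x, ...) {
  cat(sprintf(paste0("<mtld_database> %d record(s), %d MTL(s), %d site(s) ",
                     "from %d structure(s)\n"),
              length(x$records),
              sum(vapply(x$records, `[[`, logical(1), "is_mtl")),
              x$site_count, x$structure_count))
  invisible(x)
}
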