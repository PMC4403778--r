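# Synthetic PDB corpora with declared ground truth: ideal-geometry chains,
# ligands at exactly controlled nearest-atom distances, planted sequence
# identities and planted conformer RMSDs. Chemically simplistic on purpose —
# realism is a non-goal; the planted quantities are exact.

# deterministic well-separated unit vectors (golden-spiral sphere points)
fib_dir <- function(k, n = 64L) {
  z <- 1 - 2 * (k - 0.5) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(max(0, 1 - z^2))
  c(r * cos(phi), r * sin(phi), z)
}

# disjoint residue alphabets guarantee 0% identity between families
FAMILY_ALPHABETS <- c("ACDEF", "GHIKL", "MNPQR", "STVWY")

aa1to3 <- function(letters1) {
  inv <- stats::setNames(names(AA3TO1), AA3TO1)
  out <- inv[letters1]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Random self-avoiding ligand coordinates
#'
#' Builds a heavy-atom chain with 1.5-Angstrom bonds, bond angles near
#' tetrahedral and all non-adjacent pairs at least 2.2 Angstrom apart, so
#' covalent-distance bond perception recovers exactly the chain topology.
#' Optional hydrogens sit 1.0 Angstrom from their parent heavy atom (the
#' parent is always the nearest heavy atom). Uses the current RNG state.
#'
#' @param n_heavy number of heavy atoms (>= 2).
#' @param elements heavy-atom element symbols recycled to `n_heavy`
#'   (default C with some N/O).
#' @param n_h number of hydrogens to decorate (default 0), attached to the
#'   first `n_h` heavy atoms.
#' @return atom data.frame (element, name, x, y, z).
#' @export
make_ligand_coords <- function(n_heavy, elements = NULL, n_h = 0L) {
  stopifnot(n_heavy >= 2L)
  if (is.null(elements)) {
    elements <- rep(c("C", "C", "C", "N", "O"), length.out = n_heavy)
  }
  elements <- toupper(rep(elements, length.out = n_heavy))
  pos <- matrix(NA_real_, n_heavy, 3)
  pos[1, ] <- c(0, 0, 0)
  pos[2, ] <- c(1.5, 0, 0)
  for (i in seq_len(n_heavy)[-(1:2)]) {
    back_bond <- pos[i - 2, ] - pos[i - 1, ]
    repeat {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      # bond angle at atom i-1; wide-open angles keep 1-3 distances >= 2.2
      ang <- acos(sum(v * back_bond) / sqrt(sum(back_bond^2))) * 180 / pi
      if (ang < 100 || ang > 145) next
      cand <- pos[i - 1, ] + 1.5 * v
      d <- sqrt(rowSums(sweep(pos[seq_len(i - 2), , drop = FALSE], 2,
                              cand)^2))
      if (all(d >= 2.2)) {
        pos[i, ] <- cand
        break
      }
    }
  }
  atoms <- data.frame(element = elements,
                      name = paste0(elements, seq_len(n_heavy)),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  if (n_h > 0L) {
    stopifnot(n_h <= n_heavy)
    for (k in seq_len(n_h)) {
      repeat {
        v <- stats::rnorm(3)
        v <- v / sqrt(sum(v^2))
        hpos <- pos[k, ] + 1.0 * v
        d <- sqrt(rowSums(sweep(pos, 2, hpos)^2))
        if (sum(d < 1.3) == 1L) break  # only the parent is that close
      }
      atoms <- rbind(atoms, data.frame(
        element = "H", name = paste0("H", k),
        x = hpos[1], y = hpos[2], z = hpos[3], stringsAsFactors = FALSE))
    }
  }
  atoms
}

#' Generate one synthetic protein-ligand complex as PDB text
#'
#' Each chain is laid out far from every ligand by default; residues listed
#' in a ligand's `contacts` are re-placed on well-separated rays so that the
#' residue's nearest-atom distance to the ligand equals the requested
#' distance exactly (the CA sits at the requested distance from the extremal
#' ligand atom along the ray; N, C and O sit strictly farther out). The
#' construction is pure: the same entry always yields identical text.
#'
#' @param structure_id 4-character id.
#' @param chains list of `list(chain_id, sequence)` (one-letter codes).
#' @param ligands list of `list(component_id, atoms, contacts)` where
#'   `atoms` comes from [make_ligand_coords()] (or any element/name/x/y/z
#'   data.frame) and `contacts` is a data.frame with columns `chain`,
#'   `res_index`, `distance` (Angstrom).
#' @param resolution Angstrom written to REMARK 2 (`NA` writes NOT
#'   APPLICABLE).
#' @param method EXPDTA text (default X-RAY DIFFRACTION).
#' @param n_waters number of far-away water molecules (default 0).
#' @return PDB text (character scalar).
#' @export
make_complex <- function(structure_id, chains, ligands = list(),
                         resolution = 2.0, method = "X-RAY DIFFRACTION",
                         n_waters = 0L) {
  stopifnot(nchar(structure_id) == 4L)
  lig_coords <- list()
  for (j in seq_along(ligands)) {
    at <- ligands[[j]]$atoms
    offset <- c(0, 0, 150 * (j - 1))
    at$x <- at$x + offset[1]; at$y <- at$y + offset[2]; at$z <- at$z + offset[3]
    lig_coords[[j]] <- at
  }

  # default residue anchor, far from every ligand
  res_anchor <- function(chain_idx, res_idx) {
    c(90 + 7.5 * res_idx, 60 * chain_idx + 40, -80)
  }

  rows <- list()
  serial <- 0L
  push <- function(record, name, resname, chain, resseq, x, y, z, element) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      record = record, serial = serial, name = name, alt_loc = "",
      resname = resname, chain = chain, resseq = resseq, icode = "",
      x = x, y = y, z = z, occupancy = 1.0, element = element,
      stringsAsFactors = FALSE)
  }

  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    letters1 <- strsplit(ch$sequence, "")[[1]]
    res3 <- aa1to3(letters1)
    placement <- lapply(seq_along(letters1),
                        function(i) res_anchor(ci, i))
    # re-place contact residues of this chain
    contact_no <- 0L
    for (j in seq_along(ligands)) {
      contacts <- ligands[[j]]$contacts
      if (is.null(contacts) || nrow(contacts) == 0L) next
      for (k in seq_len(nrow(contacts))) {
        if (contacts$chain[k] != ch$chain_id) next
        contact_no <- contact_no + 1L
        d <- contacts$distance[k]
        if (d < 2.0) stop("requested contact distance below clash limit")
        i <- contacts$res_index[k]
        stopifnot(i >= 1L, i <= length(letters1))
        at <- lig_coords[[j]]
        u <- fib_dir(contact_no + 8L * (j - 1L))
        centroid <- c(mean(at$x), mean(at$y), mean(at$z))
        proj <- (at$x - centroid[1]) * u[1] + (at$y - centroid[2]) * u[2] +
          (at$z - centroid[3]) * u[3]
        a_star <- which.max(proj)
        anchor <- c(at$x[a_star], at$y[a_star], at$z[a_star])
        placement[[i]] <- anchor + d * u
        attr(placement[[i]], "dir") <- u
      }
    }
    for (i in seq_along(letters1)) {
      ca <- placement[[i]]
      u <- attr(ca, "dir")
      if (is.null(u)) u <- c(0, 0, 1)
      push("polymer", "CA", res3[i], ch$chain_id, i,
           ca[1], ca[2], ca[3], "C")
      push("polymer", "N", res3[i], ch$chain_id, i,
           ca[1] + 0.8 * u[1], ca[2] + 0.8 * u[2], ca[3] + 0.8 * u[3], "N")
      push("polymer", "C", res3[i], ch$chain_id, i,
           ca[1] + 1.6 * u[1], ca[2] + 1.6 * u[2], ca[3] + 1.6 * u[3], "C")
      push("polymer", "O", res3[i], ch$chain_id, i,
           ca[1] + 2.4 * u[1], ca[2] + 2.4 * u[2], ca[3] + 2.4 * u[3], "O")
    }
  }

  for (j in seq_along(ligands)) {
    at <- lig_coords[[j]]
    for (i in seq_len(nrow(at))) {
      push("hetero", at$name[i], ligands[[j]]$component_id, "X", j,
           at$x[i], at$y[i], at$z[i], at$element[i])
    }
  }
  if (n_waters > 0L) {
    for (i in seq_len(n_waters)) {
      push("hetero", "O", "HOH", "W", i, -60 - 3 * i, -60, -60, "O")
    }
  }

  atoms <- do.call(rbind, rows)
  header <- sprintf("HEADER    %-40s%-9s   %s",
                    "SYNTHETIC MTL FIXTURE", "01-JAN-13", structure_id)
  remark2 <- if (is.na(resolution)) {
    "REMARK   2 RESOLUTION. NOT APPLICABLE."
  } else {
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution)
  }
  body <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    format_pdb_atom_line(a$record, a$serial, a$name, a$alt_loc, a$resname,
                         a$chain, a$resseq, a$icode, a$x, a$y, a$z,
                         a$occupancy, a$element)
  }, character(1))
  paste(c(header, sprintf("EXPDTA    %s", method), remark2, body, "END"),
        collapse = "\n")
}

#' Perturb a conformer to a planted superposition RMSD
#'
#' Displaces heavy atoms along a random direction lying in the orthogonal
#' complement of the rigid-motion subspace (zero net translation, zero net
#' rotation at first order), then rescales the displacement by bisection
#' until the optimal-superposition RMSD to the base equals `planted_rmsd`,
#' and finally applies a random proper rigid motion. With `planted_rmsd = 0`
#' only the rigid motion is applied. Uses the current RNG state.
#'
#' @param atoms atom data.frame with element/x/y/z (heavy atoms only are
#'   displaced; an all-heavy table is expected).
#' @param planted_rmsd target RMSD in Angstrom (>= 0).
#' @return atom data.frame of the new conformer (same names/elements).
#' @export
make_conformer_pair <- function(atoms, planted_rmsd) {
  stopifnot(planted_rmsd >= 0)
  X <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(X)
  stopifnot(n >= 3L)
  Y <- X
  if (planted_rmsd > 0) {
    Xc <- sweep(X, 2, colMeans(X))
    # basis of infinitesimal rigid motions: 3 translations + 3 rotations
    basis <- matrix(0, 3 * n, 6)
    for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
    for (i in seq_len(n)) {
      xi <- Xc[i, ]
      basis[(3 * i - 2):(3 * i), 4] <- c(0, -xi[3], xi[2])
      basis[(3 * i - 2):(3 * i), 5] <- c(xi[3], 0, -xi[1])
      basis[(3 * i - 2):(3 * i), 6] <- c(-xi[2], xi[1], 0)
    }
    Q <- qr.Q(qr(basis))
    d <- stats::rnorm(3 * n)
    d <- d - Q %*% (t(Q) %*% d)
    D <- matrix(d, n, 3, byrow = TRUE)
    D <- D / sqrt(mean(rowSums(D^2)))
    f <- function(s) kabsch_superpose(X, X + s * D)$rmsd
    hi <- planted_rmsd
    while (f(hi) < planted_rmsd) hi <- hi * 2
    lo <- 0
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < planted_rmsd) lo <- mid else hi <- mid
    }
    Y <- X + ((lo + hi) / 2) * D
  }
  # random proper rigid motion
  M <- matrix(stats::rnorm(9), 3)
  qrM <- qr(M)
  R <- qr.Q(qrM) %*% diag(sign(diag(qr.R(qrM))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- stats::runif(3, -20, 20)
  Y <- Y %*% t(R) + matrix(t_vec, nrow(Y), 3, byrow = TRUE)
  out <- atoms
  out$x <- Y[, 1]; out$y <- Y[, 2]; out$z <- Y[, 3]
  out
}

#' Chain table with planted family structure
#'
#' Generates `n_chains` sequences falling into `n_families` families:
#' members of a family differ at a small mutated fraction (identity well
#' above any reasonable redundancy threshold) while families use disjoint
#' residue alphabets (identity 0 between families). Family sizes are as
#' even as possible; the truth assignment is returned.
#'
#' @param n_chains total chains.
#' @param n_families number of families (<= 4).
#' @param seed RNG seed.
#' @param length sequence length (default 60).
#' @param mutate_frac fraction of positions mutated per member (default
#'   0.05).
#' @return list with `chains` (data.frame key, sequence) and `family`
#'   (integer truth assignment).
#' @export
make_target_family_chains <- function(n_chains, n_families, seed,
                                      length = 60L, mutate_frac = 0.05) {
  stopifnot(n_families <= base::length(FAMILY_ALPHABETS))
  set.seed(seed)
  fam_of <- sort(rep_len(seq_len(n_families), n_chains))
  seqs <- character(n_chains)
  parents <- lapply(seq_len(n_families), function(f) {
    sample(strsplit(FAMILY_ALPHABETS[f], "")[[1]], length, replace = TRUE)
  })
  for (i in seq_len(n_chains)) {
    f <- fam_of[i]
    s <- parents[[f]]
    n_mut <- max(1L, round(mutate_frac * length))
    pos <- sample(length, n_mut)
    alpha <- strsplit(FAMILY_ALPHABETS[f], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(alpha, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  list(chains = data.frame(key = sprintf("C%03d_A", seq_len(n_chains)),
                           sequence = seqs, stringsAsFactors = FALSE),
       family = fam_of)
}

#' Random corpus specification with declared ground truth
#'
#' Draws a corpus plan under one seed: a few multi-target components whose
#' complexes bind chains from 2-3 unrelated families (MTL), one or two
#' redundant components binding near-identical chains (not an MTL under
#' filtration), optional single-structure components (dropped at the
#' multi-structure gate) and optionally a component confined to structures
#' failing the resolution gate. One complex per structure; each complex gets
#' 6-9 contact residues inside the site radius and up to 2 outside it; at
#' most one conformer per component carries a planted RMSD, the rest are
#' rigid copies, so the component's true maximal pairwise RMSD equals the
#' planted value.
#'
#' @param seed integer seed.
#' @return `fixture_spec` list (fully determined plan; see
#'   [make_corpus()]).
#' @export
random_corpus_spec <- function(seed) {
  set.seed(seed)
  comp_no <- 0L
  next_comp <- function() {
    comp_no <<- comp_no + 1L
    sprintf("L%02d", comp_no)
  }
  plan <- list()
  n_mtl <- sample(1:3, 1)
  n_red <- sample(1:2, 1)
  n_single <- sample(0:2, 1)
  n_doomed <- sample(0:1, 1)

  add_component <- function(role, n_cplx, families) {
    comp <- next_comp()
    planted <- if (n_cplx >= 2L) {
      if (stats::runif(1) < 0.4) 0 else round(stats::runif(1, 0.5, 3.0), 2)
    } else {
      0
    }
    cplx <- lapply(seq_len(n_cplx), function(i) {
      n_close <- sample(6:9, 1)
      n_far <- sample(0:2, 1)
      list(family = families[i],
           resolution = if (role == "doomed") 3.5 else
             round(stats::runif(1, 1.3, 2.7), 2),
           close_dist = round(stats::runif(n_close, 3.2, 5.7), 2),
           far_dist = if (n_far > 0) round(stats::runif(n_far, 6.6, 8.5), 2)
           else numeric(0),
           n_waters = sample(0:3, 1))
    })
    plan[[comp]] <<- list(component_id = comp, role = role,
                          n_heavy = sample(9:14, 1),
                          planted_rmsd = planted, complexes = cplx)
  }

  for (k in seq_len(n_mtl)) {
    n_fam <- sample(2:3, 1)
    n_cplx <- sample(n_fam:4, 1)
    families <- c(seq_len(n_fam), sample(seq_len(n_fam),
                                         n_cplx - n_fam, replace = TRUE))
    add_component("mtl", n_cplx, sample(families))
  }
  for (k in seq_len(n_red)) add_component("redundant", 2L, c(1L, 1L))
  if (n_single > 0) {
    for (k in seq_len(n_single)) add_component("single", 1L, 1L)
  }
  if (n_doomed > 0) add_component("doomed", 2L, c(1L, 2L))

  structure(list(seed = seed, components = plan), class = "fixture_spec")
}

#' Materialize a corpus spec into PDB files plus a truth table
#'
#' Writes one PDB file per complex (duplicate structure ids in the spec are
#' an error) and `truth.json` declaring, per component: whether the
#' component survives to the database, its non-redundant cluster count, its
#' MTL status with filtration on and off, the planted maximal conformer
#' RMSD, and the expected site residue set of every complex. Corpus bytes
#' are a pure function of the spec (all randomness is re-seeded from
#' `spec$seed`).
#'
#' @param spec `fixture_spec` from [random_corpus_spec()].
#' @param out_dir output directory (created).
#' @return the truth table, invisibly also written to
#'   `file.path(out_dir, "truth.json")`.
#' @export
make_corpus <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 104729L)
  truth <- list()
  struct_no <- 0L
  seen_ids <- character(0)

  for (comp in names(spec$components)) {
    cp <- spec$components[[comp]]
    base_atoms <- make_ligand_coords(cp$n_heavy)
    seq_len_aa <- 40L
    # per-family parent sequences for this component
    fams <- sort(unique(vapply(cp$complexes, `[[`, integer(1), "family")))
    parents <- lapply(fams, function(f) {
      sample(strsplit(FAMILY_ALPHABETS[f], "")[[1]], seq_len_aa,
             replace = TRUE)
    })
    names(parents) <- as.character(fams)
    perturbed_at <- if (length(cp$complexes) >= 2L && cp$planted_rmsd > 0) {
      2L
    } else {
      0L
    }

    comp_truth <- list(component_id = comp, role = cp$role,
                       n_complexes = length(cp$complexes),
                       cluster_count = length(fams),
                       planted_max_rmsd = cp$planted_rmsd,
                       complexes = list())

    for (i in seq_along(cp$complexes)) {
      cx <- cp$complexes[[i]]
      struct_no <- struct_no + 1L
      sid <- sprintf("S%03d", struct_no)
      if (sid %in% seen_ids) stop("duplicate structure id in spec")
      seen_ids <- c(seen_ids, sid)

      # mutate the family parent at 2 positions -> ~95% identity in-family
      s <- parents[[as.character(cx$family)]]
      alpha <- strsplit(FAMILY_ALPHABETS[cx$family], "")[[1]]
      for (p in sample(seq_len_aa, 2L)) s[p] <- sample(setdiff(alpha, s[p]), 1)
      sequence <- paste(s, collapse = "")

      atoms <- if (i == 1L) {
        base_atoms
      } else {
        make_conformer_pair(base_atoms,
                            if (i == perturbed_at) cp$planted_rmsd else 0)
      }
      dists <- c(cx$close_dist, cx$far_dist)
      n_res <- length(dists)
      contacts <- data.frame(chain = rep("A", n_res),
                             res_index = sample(seq_len_aa, n_res),
                             distance = dists, stringsAsFactors = FALSE)
      txt <- make_complex(
        structure_id = sid,
        chains = list(list(chain_id = "A", sequence = sequence)),
        ligands = list(list(component_id = comp, atoms = atoms,
                            contacts = contacts)),
        resolution = cx$resolution, n_waters = cx$n_waters)
      writeLines(txt, file.path(out_dir, paste0(sid, ".pdb")))

      comp_truth$complexes[[sid]] <- list(
        structure_id = sid, family = cx$family,
        resolution = cx$resolution,
        site_resseq = sort(contacts$res_index[contacts$distance <= 6.0]),
        passes_resolution = cx$resolution < 3.0)
    }

    surviving <- sum(vapply(comp_truth$complexes, `[[`, logical(1),
                            "passes_resolution"))
    comp_truth$in_db <- surviving >= 2L
    comp_truth$is_mtl_filtration_on <- comp_truth$in_db &&
      comp_truth$cluster_count >= 2L
    comp_truth$is_mtl_filtration_off <- comp_truth$in_db && surviving >= 2L
    truth[[comp]] <- comp_truth
  }

  out <- list(seed = spec$seed, components = truth)
  jsonlite::write_json(out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
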