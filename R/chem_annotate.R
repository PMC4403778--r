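# Chemical annotation: distance-based bond perception, molecular weight,
# Lipinski rule-of-five descriptors, path fingerprints with Tanimoto
# similarity, connectivity-level SMILES.

#' Covalent radii (Angstrom) used for bond perception
#' @keywords internal
COVALENT_RADII <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA_ = NA, # placeholder removed below
  P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
  SI = 1.11, AS = 1.19, LI = 1.28, MG = 1.41, AL = 1.21, K = 2.03,
  CA = 1.76, MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32,
  ZN = 1.22, MO = 1.54, CD = 1.44, HG = 1.32, PT = 1.36, AU = 1.36,
  AG = 1.45
)
COVALENT_RADII <- COVALENT_RADII[!is.na(COVALENT_RADII)]
names(COVALENT_RADII)[names(COVALENT_RADII) == "NA_"] <- "NA"
COVALENT_RADII <- c(COVALENT_RADII, "NA" = 1.66)

#' Standard atomic weights (Da)
#' @keywords internal
ATOMIC_WEIGHTS <- c(
  H = 1.008, D = 2.014, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, "NA" = 22.990, MG = 24.305, AL = 26.982, SI = 28.085,
  P = 30.974, S = 32.06, CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  SE = 78.971, BR = 79.904, MO = 95.95, AG = 107.868, CD = 112.414,
  I = 126.904, PT = 195.084, AU = 196.967, HG = 200.592, LI = 6.94,
  AS = 74.922
)

#' Build a molecular graph from coordinates by covalent-distance perception
#'
#' Two heavy atoms are bonded iff their distance is at most the sum of their
#' covalent radii plus `tolerance` (default 0.45 Angstrom, common perception
#' practice). A hydrogen (or deuterium) is bonded only to its single nearest
#' heavy atom. Bond orders are not perceived: the graph carries
#' element-labeled topology only.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (an atom
#'   table from [parse_structure()] works; an optional `name` column is
#'   carried through).
#' @param component_id optional chemical component id stored on the graph.
#' @param tolerance covalent-distance slack in Angstrom (default 0.45).
#' @return `molecular_graph`: `atoms` (data.frame element, name), `bonds`
#'   (two-column integer matrix, i < j, no duplicates), `component_id`,
#'   `n_fragments` (connected components over all atoms).
#' @export
perceive_bonds <- function(atoms, component_id = NA_character_,
                           tolerance = 0.45) {
  stopifnot(nrow(atoms) >= 1L)
  el <- toupper(atoms$element)
  unknown <- setdiff(unique(el), names(COVALENT_RADII))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  n <- nrow(atoms)
  is_h <- el %in% c("H", "D")
  bonds <- matrix(integer(0), ncol = 2)
  if (n > 1L) {
    dmat <- as.matrix(stats::dist(xyz))
    radii <- COVALENT_RADII[el]
    thresh <- outer(radii, radii, `+`) + tolerance
    heavy <- which(!is_h)
    if (length(heavy) > 1L) {
      sub <- dmat[heavy, heavy, drop = FALSE] <= thresh[heavy, heavy, drop = FALSE]
      idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
      bonds <- cbind(heavy[idx[, 1]], heavy[idx[, 2]])
    }
    for (h in which(is_h)) {
      if (length(heavy) == 0L) next
      nearest <- heavy[which.min(dmat[h, heavy])]
      bonds <- rbind(bonds, c(min(h, nearest), max(h, nearest)))
    }
  }
  bonds <- bonds[bonds[, 1] != bonds[, 2], , drop = FALSE]
  if (nrow(bonds) > 1L) {
    bonds <- unique(bonds)
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  g_atoms <- data.frame(
    element = el,
    name = if ("name" %in% names(atoms)) atoms$name else
      paste0(el, seq_len(n)),
    stringsAsFactors = FALSE)
  structure(
    list(atoms = g_atoms, bonds = bonds, component_id = component_id,
         n_fragments = count_fragments(n, bonds)),
    class = "molecular_graph")
}

#' Construct a molecular graph directly from elements and bonds
#'
#' Used when topology is already known (tests, fixtures) and no coordinate
#' perception is wanted.
#' @param elements character vector of element symbols.
#' @param bonds two-column matrix of 1-based atom index pairs.
#' @param component_id optional id.
#' @return `molecular_graph`.
#' @export
molecular_graph <- function(elements, bonds, component_id = NA_character_) {
  elements <- toupper(elements)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0L) {
    stopifnot(all(bonds >= 1), all(bonds <= length(elements)),
              all(bonds[, 1] != bonds[, 2]))
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  structure(
    list(atoms = data.frame(element = elements,
                            name = paste0(elements, seq_along(elements)),
                            stringsAsFactors = FALSE),
         bonds = bonds, component_id = component_id,
         n_fragments = count_fragments(length(elements), bonds)),
    class = "molecular_graph")
}

count_fragments <- function(n, bonds) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      ri <- find(bonds[k, 1]); rj <- find(bonds[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

adjacency_list <- function(g, heavy_only = TRUE) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(g$bonds) > 0L) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  if (heavy_only) {
    is_h <- g$atoms$element %in% c("H", "D")
    adj <- lapply(adj, function(v) v[!is_h[v]])
  }
  adj
}

#' Molecular weight of a graph
#'
#' Sum of standard atomic weights over all atoms, hydrogens included when
#' present in the graph.
#' @param g `molecular_graph`.
#' @return weight in Da.
#' @export
molecular_weight <- function(g) {
  sum(ATOMIC_WEIGHTS[g$atoms$element])
}

#' Lipinski rule-of-five descriptors and drug-likeness call
#'
#' Hydrogen-bond donors are counted as O-H and N-H bonds. When the graph
#' carries explicit hydrogens, donor hydrogens are counted directly; when no
#' hydrogen is present, each N/O contributes `max(0, default valence -
#' heavy degree)` implicit donor hydrogens (valence 3 for N, 2 for O).
#' Acceptors are the N and O atom count. Violations are counted over the
#' evaluable criteria MW > 500 Da, donors > 5, acceptors > 10, and logP > 5
#' when a logP value is supplied (the criterion is skipped, never guessed,
#' when it is not). Drug-like means at most one violation.
#'
#' @param g `molecular_graph`.
#' @param logp optional numeric logP from an external provider.
#' @return `descriptors`: `molecular_weight`, `hbd`, `hba`, `logp` (`NA`
#'   when absent), `lipinski_violations`, `druglike`.
#' @export
lipinski <- function(g, logp = NULL) {
  el <- g$atoms$element
  has_h <- any(el %in% c("H", "D"))
  if (has_h) {
    hbd <- 0L
    if (nrow(g$bonds) > 0L) {
      e1 <- el[g$bonds[, 1]]; e2 <- el[g$bonds[, 2]]
      hbd <- sum((e1 %in% c("H", "D") & e2 %in% c("N", "O")) |
                   (e2 %in% c("H", "D") & e1 %in% c("N", "O")))
    }
  } else {
    deg <- integer(length(el))
    if (nrow(g$bonds) > 0L) {
      tab <- table(factor(c(g$bonds[, 1], g$bonds[, 2]),
                          levels = seq_along(el)))
      deg <- as.integer(tab)
    }
    val <- ifelse(el == "N", 3L, ifelse(el == "O", 2L, 0L))
    hbd <- sum(pmax(0L, val - deg)[el %in% c("N", "O")])
  }
  hba <- sum(el %in% c("N", "O"))
  mw <- molecular_weight(g)
  violations <- sum(mw > 500, hbd > 5, hba > 10)
  logp_val <- NA_real_
  if (!is.null(logp) && is.finite(logp)) {
    logp_val <- logp
    violations <- violations + (logp > 5)
  }
  structure(
    list(molecular_weight = mw, hbd = as.integer(hbd), hba = as.integer(hba),
         logp = logp_val, lipinski_violations = as.integer(violations),
         druglike = violations <= 1L),
    class = "descriptors")
}

# deterministic 31-polynomial string hash; kept in double precision, all
# intermediates < 2^53
FINGERPRINT_HASH_VERSION <- "poly31-v1"
hash_string <- function(s, n_bits) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% n_bits) + 1L
}

#' Enumerate canonical linear heavy-atom paths of a graph
#'
#' All simple paths of 1..`max_path_len` heavy atoms; each path is encoded
#' as its element sequence and canonicalized as the lexicographic minimum of
#' the forward and reverse encodings; the unique set is returned.
#' @param g `molecular_graph`.
#' @param max_path_len maximum path length in atoms (default 7).
#' @return character vector of canonical path strings (e.g. `"C-N-O"`).
#' @export
enumerate_paths <- function(g, max_path_len = 7L) {
  el <- g$atoms$element
  heavy <- which(!(el %in% c("H", "D")))
  if (length(heavy) == 0L) return(character(0))
  adj <- adjacency_list(g, heavy_only = TRUE)
  paths <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(path) {
    fwd <- paste(el[path], collapse = "-")
    rev_ <- paste(rev(el[path]), collapse = "-")
    assign(min(fwd, rev_), TRUE, envir = paths)
    if (length(path) == max_path_len) return()
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  for (a in heavy) walk(a)
  sort(ls(paths), method = "radix")
}

#' Path-based molecular fingerprint
#'
#' Hashes every canonical linear heavy-atom path of 1..`max_path_len` atoms
#' into a fixed-length bitset. Deterministic; invariant under atom
#' reindexing. This is an FP2-style fingerprint — element-labeled topology
#' only, no bond orders — not a bit-compatible Open Babel FP2.
#'
#' @param g `molecular_graph`.
#' @param max_path_len maximum path length in atoms (default 7).
#' @param n_bits bitset length (default 1024).
#' @return `fingerprint`: `bits` (sorted 1-based set-bit indices), `n_bits`,
#'   `n_set`, `max_path_len`, `hash_version`.
#' @export
path_fingerprint <- function(g, max_path_len = 7L, n_bits = 1024L) {
  paths <- enumerate_paths(g, max_path_len)
  bits <- sort(unique(vapply(paths, hash_string, integer(1),
                             n_bits = n_bits, USE.NAMES = FALSE)))
  structure(
    list(bits = bits, n_bits = as.integer(n_bits),
         n_set = length(bits), max_path_len = as.integer(max_path_len),
         hash_version = FINGERPRINT_HASH_VERSION),
    class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1.0 when both bitsets are
#' empty. Bitset lengths must agree.
#' @param a,b `fingerprint` objects.
#' @return value in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (a$n_bits != b$n_bits) stop("fingerprint length mismatch")
  un <- length(union(a$bits, b$bits))
  if (un == 0L) return(1.0)
  length(intersect(a$bits, b$bits)) / un
}

#' Rank database ligands by structural similarity to a query
#'
#' Hits are records whose fingerprint Tanimoto similarity to the query is at
#' least `cutoff`, sorted by score descending then component id ascending.
#'
#' @param query `molecular_graph` or `fingerprint`.
#' @param records list of ligand records, each carrying `component_id` and
#'   `fingerprint` (an [mtld_database()] `records` list works).
#' @param cutoff Tanimoto cutoff in \[0, 1\] (default 0.8).
#' @return data.frame with columns `component_id`, `tanimoto`, ordered.
#' @export
similarity_search <- function(query, records, cutoff = 0.8) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  qfp <- if (inherits(query, "fingerprint")) query else path_fingerprint(query)
  ids <- vapply(records, function(r) r$component_id, character(1))
  scores <- vapply(records, function(r) tanimoto(qfp, r$fingerprint),
                   numeric(1))
  keep <- scores >= cutoff
  out <- data.frame(component_id = ids[keep], tanimoto = scores[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$tanimoto, out$component_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connectivity-level SMILES of a molecular graph
#'
#' Heavy atoms only, written as bracket atoms (`[C]`, `[N]`, ...) with
#' single bonds and ring-closure digits; no aromaticity, bond orders or
#' stereochemistry. Disconnected fragments are dot-separated. Parsing the
#' result with any standard SMILES reader reproduces the heavy-atom element
#' multiset and bond count.
#'
#' @param g `molecular_graph` with perceived or declared bonds.
#' @return SMILES text.
#' @export
to_smiles <- function(g) {
  el <- g$atoms$element
  heavy <- which(!(el %in% c("H", "D")))
  if (length(heavy) == 0L) stop("no heavy atoms to write")
  adj <- adjacency_list(g, heavy_only = TRUE)

  visited <- rep(FALSE, nrow(g$atoms))
  ring_bonds <- list()   # per atom: ring digit labels
  ring_digit <- 0L
  ring_open <- new.env(hash = TRUE, parent = emptyenv())
  atom_ring <- vector("list", nrow(g$atoms))

  # first DFS pass: find back edges, assign ring-closure digits
  mark_rings <- function(start) {
    stack <- list(c(start, 0L))
    parent <- rep(0L, nrow(g$atoms))
    order_seen <- rep(0L, nrow(g$atoms))
    cnt <- 0L
    dfs <- function(v, p) {
      cnt <<- cnt + 1L
      order_seen[v] <<- cnt
      for (w in adj[[v]]) {
        if (w == p) next
        if (order_seen[w] == 0L) {
          parent[w] <<- v
          dfs(w, v)
        } else if (order_seen[w] < order_seen[v]) {
          ring_digit <<- ring_digit + 1L
          atom_ring[[v]] <<- c(atom_ring[[v]], ring_digit)
          atom_ring[[w]] <<- c(atom_ring[[w]], ring_digit)
        }
      }
    }
    dfs(start, 0L)
    order_seen
  }

  ring_label <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  emit <- function(v, p) {
    visited[v] <<- TRUE
    s <- paste0("[", el[v], "]",
                paste(vapply(atom_ring[[v]], ring_label, character(1)),
                      collapse = ""))
    children <- adj[[v]][adj[[v]] != p & !visited[adj[[v]]]]
    # drop ring-closure partners already handled via digits
    children <- children[!duplicated(children)]
    children <- children[!visited[children]]
    if (length(children) > 0L) {
      parts <- character(0)
      for (k in seq_along(children)) {
        w <- children[k]
        if (visited[w]) next
        sub <- emit(w, v)
        parts <- c(parts, sub)
      }
      if (length(parts) > 1L) {
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""),
                    parts[length(parts)])
      } else if (length(parts) == 1L) {
        s <- paste0(s, parts)
      }
    }
    s
  }

  frags <- character(0)
  for (a in heavy) {
    if (!visited[a]) {
      mark_rings(a)
      frags <- c(frags, emit(a, 0L))
    }
  }
  paste(frags, collapse = ".")
}

#' Export descriptors for a set of records as TSV
#' @param records list with `component_id` and `descriptors`.
#' @param path output path; `NULL` returns text.
#' @export
write_descriptor_tsv <- function(records, path = NULL) {
  lines <- c(
    "component_id\tmolecular_weight\thbd\thba\tlogp\tlipinski_violations\tdruglike",
    vapply(records, function(r) {
      d <- r$descriptors
      sprintf("%s\t%.3f\t%d\t%d\t%s\t%d\t%s", r$component_id,
              d$molecular_weight, d$hbd, d$hba,
              ifelse(is.na(d$logp), "NA", sprintf("%.3f", d$logp)),
              d$lipinski_violations, ifelse(d$druglike, "TRUE", "FALSE"))
    }, character(1)))
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Fingerprint as a hex string (for TSV export)
#' @param fp `fingerprint`.
#' @return hex text, most significant bit = bit 1.
#' @export
fingerprint_hex <- function(fp) {
  words <- integer(ceiling(fp$n_bits / 4))
  for (b in fp$bits) {
    w <- (b - 1L) %/% 4L + 1L
    words[w] <- bitwOr(words[w], bitwShiftL(1L, 3L - (b - 1L) %% 4L))
  }
  paste(sprintf("%x", words), collapse = "")
}
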