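# Conformational variability of a ligand across its complexes: atom
# correspondence by name, Kabsch least-squares superposition, pairwise RMSD
# matrix and the max-RMSD flexibility criterion.

#' Match atoms of two conformers of the same chemical component
#'
#' Heavy atoms are paired by identical atom name; atoms absent from either
#' side are dropped. Order follows the first instance's atom order. Fewer
#' than 3 matched atoms make the superposition under-determined and raise an
#' error.
#'
#' @param a,b `ligand_instance` objects sharing a component id.
#' @return two-column integer matrix of row indices into `a$atoms` and
#'   `b$atoms`.
#' @export
match_atoms <- function(a, b) {
  if (a$component_id != b$component_id) {
    stop("cannot match atoms across different components")
  }
  heavy_a <- which(!(toupper(a$atoms$element) %in% c("H", "D")))
  heavy_b <- which(!(toupper(b$atoms$element) %in% c("H", "D")))
  names_a <- a$atoms$name[heavy_a]
  names_b <- b$atoms$name[heavy_b]
  # duplicate names: keep first occurrence on each side
  keep_a <- heavy_a[!duplicated(names_a)]
  keep_b <- heavy_b[!duplicated(names_b)]
  names_a <- a$atoms$name[keep_a]
  names_b <- b$atoms$name[keep_b]
  common <- names_a[names_a %in% names_b]
  if (length(common) < 3L) {
    stop(sprintf("only %d matched atoms: superposition under-determined",
                 length(common)))
  }
  cbind(a = keep_a[match(common, names_a)],
        b = keep_b[match(common, names_b)])
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Returns the least-squares optimal proper rigid motion mapping `coords_b`
#' onto `coords_a` and the residual RMSD. The rotation is guaranteed proper
#' (determinant +1): mirror images never superpose to zero.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (N >= 3), rows matched.
#' @return `superposition`: `rotation` (3x3), `translation` (length 3;
#'   transformed b = `coords_b %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom) and `matched_atom_count`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3L, ncol(coords_b) == 3L,
            nrow(coords_a) == nrow(coords_b), nrow(coords_a) >= 3L)
  if (any(!is.finite(coords_a)) || any(!is.finite(coords_b))) {
    stop("non-finite coordinates")
  }
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  C <- t(B) %*% A
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Brot <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - Brot)^2)))
  structure(
    list(rotation = R,
         translation = as.numeric(ca - R %*% cb),
         rmsd = rmsd,
         matched_atom_count = nrow(coords_a)),
    class = "superposition")
}

#' RMSD between two conformers after name matching and superposition
#' @param a,b `ligand_instance` objects of one component.
#' @return RMSD in Angstrom.
#' @export
conformer_rmsd <- function(a, b) {
  idx <- match_atoms(a, b)
  kabsch_superpose(as.matrix(a$atoms[idx[, "a"], c("x", "y", "z")]),
                   as.matrix(b$atoms[idx[, "b"], c("x", "y", "z")]))$rmsd
}

#' Conformational-variability report for one chemical component
#'
#' Computes the full pairwise RMSD matrix over all matchable conformer pairs
#' and classifies the component as rigid iff the maximal pairwise RMSD is
#' `<= class_cutoff` (inclusive, default 2.0 Angstrom). Pairs that cannot be
#' matched (fewer than 3 shared heavy-atom names) are recorded as `NA` and
#' excluded from the maximum; when no pair is matchable the class is
#' `"undetermined"`.
#'
#' @param instances list of >= 2 `ligand_instance` of one component.
#' @param class_cutoff rigid/flexible cutoff in Angstrom (default 2.0).
#' @return `conformer_report`: `component_id`, `conformer_keys`,
#'   `pairwise_rmsd` (symmetric matrix, diagonal 0), `max_rmsd` (`NA` when
#'   undetermined) and `flexibility_class`.
#' @export
conformer_report <- function(instances, class_cutoff = 2.0) {
  stopifnot(length(instances) >= 2L)
  comp <- unique(vapply(instances, function(x) x$component_id, character(1)))
  if (length(comp) != 1L) stop("instances span multiple components")
  keys <- vapply(instances, function(x) {
    sprintf("%s_%s_%s_%d", x$source_structure_id, x$component_id,
            x$chain_id, x$residue_seq)
  }, character(1))
  n <- length(instances)
  m <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- tryCatch(conformer_rmsd(instances[[i]], instances[[j]]),
                    error = function(e) NA_real_)
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  upper <- m[upper.tri(m)]
  max_rmsd <- if (all(is.na(upper))) NA_real_ else max(upper, na.rm = TRUE)
  cls <- if (is.na(max_rmsd)) {
    "undetermined"
  } else if (max_rmsd <= class_cutoff) {
    "rigid"
  } else {
    "flexible"
  }
  structure(
    list(component_id = comp, conformer_keys = keys, pairwise_rmsd = m,
         max_rmsd = max_rmsd, flexibility_class = cls),
    class = "conformer_report")
}

#' @export
print.conformer_report <- function(x, ...) {
  cat(sprintf("<conformer_report %s> %d conformers, max RMSD %s, class %s\n",
              x$component_id, length(x$conformer_keys),
              ifelse(is.na(x$max_rmsd), "NA", sprintf("%.3f", x$max_rmsd)),
              x$flexibility_class))
  invisible(x)
}
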