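# Sequence-identity redundancy removal: global alignment percent identity
# (shorter-sequence denominator) and single-linkage clustering of target
# chains at the identity threshold.

#' Percent identity between two protein sequences
#'
#' Computes a global (end-gap-penalized) alignment with BLOSUM62,
#' gap opening 10 and gap extension 0.5, then reports
#' `100 * identical aligned positions / denominator`. The default denominator
#' is the shorter sequence length (the common culling convention); set
#' `denominator = "alignment"` for alignment length.
#'
#' @param seq_a,seq_b non-empty uppercase one-letter amino-acid strings.
#' @param denominator `"shorter"` (default) or `"alignment"`.
#' @return percent identity in \[0, 100\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b, denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  ident <- Biostrings::nmatch(aln)
  denom <- if (denominator == "shorter") {
    min(nchar(seq_a), nchar(seq_b))
  } else {
    Biostrings::nchar(Biostrings::alignedPattern(aln))
  }
  min(100, 100 * ident / denom)
}

#' Pairwise identity matrix over target chains
#'
#' @param chains data.frame with columns `key` (unique chain key, e.g.
#'   `"1ABC_A"`) and `sequence`, or a named character vector of sequences.
#' @param denominator passed to [pairwise_identity()].
#' @return `identity_matrix`: symmetric numeric matrix (percent, diagonal
#'   100) with chain keys as dimnames.
#' @export
identity_matrix <- function(chains, denominator = "shorter") {
  chains <- as_chain_table(chains)
  n <- nrow(chains)
  m <- matrix(100, n, n, dimnames = list(chains$key, chains$key))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        v <- pairwise_identity(chains$sequence[i], chains$sequence[j],
                               denominator = denominator)
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  class(m) <- c("identity_matrix", class(m))
  m
}

as_chain_table <- function(chains) {
  if (is.character(chains)) {
    if (is.null(names(chains))) stop("chains vector must be named by key")
    chains <- data.frame(key = names(chains), sequence = unname(chains),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("key", "sequence") %in% names(chains)))
  if (anyDuplicated(chains$key)) stop("duplicate chain keys")
  chains
}

#' Collapse target chains into non-redundant clusters
#'
#' Single-linkage clustering: two chains are linked iff their pairwise
#' identity is `>= threshold` (so a pair at exactly the threshold is
#' redundant, matching a strict `< threshold` retention rule); clusters are
#' the connected components. The representative of a cluster is its member
#' with the longest sequence (ties broken by lexicographically smallest
#' key); clusters are ordered by representative key. The result is
#' deterministic and independent of input order.
#'
#' @param chains see [identity_matrix()].
#' @param threshold percent identity linkage threshold in (0, 100\]
#'   (default 35).
#' @param identity optional precomputed [identity_matrix()] whose dimnames
#'   cover all chain keys (it may be larger); alignments are skipped when
#'   given.
#' @return list of `target_cluster`: `members` (keys, sorted) and
#'   `representative`.
#' @export
cluster_targets <- function(chains, threshold = 35, identity = NULL) {
  stopifnot(threshold > 0, threshold <= 100)
  chains <- as_chain_table(chains)
  n <- nrow(chains)
  if (n == 0L) return(list())
  if (is.null(identity)) {
    identity <- identity_matrix(chains)
  } else {
    stopifnot(all(chains$key %in% rownames(identity)))
    identity <- identity[chains$key, chains$key, drop = FALSE]
  }

  # union-find over chain indices
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (identity[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))

  clusters <- lapply(split(seq_len(n), roots), function(idx) {
    keys <- chains$key[idx]
    lens <- nchar(chains$sequence[idx])
    cand <- keys[lens == max(lens)]
    rep_key <- sort(cand, method = "radix")[1]
    structure(list(members = sort(keys, method = "radix"),
                   representative = rep_key),
              class = "target_cluster")
  })
  ord <- order(vapply(clusters, function(cl) cl$representative, character(1)),
               method = "radix")
  unname(clusters[ord])
}

#' Non-redundant target count for a ligand's binding partners
#'
#' With filtration enabled, the number of single-linkage clusters over the
#' primary binding chains of all the ligand's qualifying complexes; with it
#' disabled, the number of distinct primary binding chains (the full list).
#'
#' @param chains chain table (key, sequence) of the ligand's primary binding
#'   chains, one row per complex (duplicate keys are collapsed first).
#' @param threshold percent identity threshold (default 35).
#' @param filtration_enabled apply redundancy filtration (default TRUE).
#' @param identity optional precomputed identity matrix.
#' @return integer target count.
#' @export
nonredundant_target_count <- function(chains, threshold = 35,
                                      filtration_enabled = TRUE,
                                      identity = NULL) {
  chains <- as_chain_table(chains)
  chains <- chains[!duplicated(chains$key), , drop = FALSE]
  if (!filtration_enabled) return(nrow(chains))
  length(cluster_targets(chains, threshold = threshold, identity = identity))
}

#' Export an identity matrix as TSV (1 decimal)
#' @param m `identity_matrix`.
#' @param path output path; `NULL` returns text.
#' @export
write_identity_tsv <- function(m, path = NULL) {
  keys <- rownames(m)
  lines <- c(paste(c("key", keys), collapse = "\t"),
             vapply(seq_along(keys), function(i) {
               paste(c(keys[i], sprintf("%.1f", m[i, ])), collapse = "\t")
             }, character(1)))
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Export clusters as a two-column TSV (chain_key, cluster_id)
#' @param clusters list of `target_cluster`.
#' @param path output path; `NULL` returns text.
#' @export
write_cluster_tsv <- function(clusters, path = NULL) {
  rows <- unlist(lapply(seq_along(clusters), function(i) {
    sprintf("%s\t%d", clusters[[i]]$members, i)
  }))
  lines <- c("chain_key\tcluster_id", rows)
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}
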