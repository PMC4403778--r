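# Pairwise identity (global alignment, shorter-sequence denominator) and
# single-linkage redundancy clustering.

test_that("identity basics: self, disjoint, symmetry, error on empty", {
  expect_equal(pairwise_identity(strrep("ACDKW", 10), strrep("ACDKW", 10)),
               100.0)
  expect_equal(pairwise_identity(strrep("A", 10), strrep("W", 10)), 0.0)
  expect_error(pairwise_identity("", "ACD"), "empty")
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    a <- paste(sample(aa, sample(10:30, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(10:30, 1), TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("alignment agrees with an independent Gotoh oracle", {
  # a 12-mer pair with one substitution and one indel region
  a <- "ACDEFGHIKLMN"
  b <- "ACDEYGHIKL"
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  orc <- oracle_gotoh(a, b)
  expect_equal(Biostrings::score(aln), orc$score)
  expect_equal(pairwise_identity(a, b), 100 * orc$nmatch / nchar(b))

  # score agreement on random short pairs (identity may be degenerate under
  # co-optimal alignments; the score is unique)
  set.seed(32)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:15) {
    a <- paste(sample(aa, sample(8:20, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:20, 1), TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), oracle_gotoh(a, b)$score)
  }

  # near-identical pairs have unambiguous ungapped optima
  for (k in 1:10) {
    a <- paste(sample(aa, 40, TRUE), collapse = "")
    bvec <- strsplit(a, "")[[1]]
    pos <- sample(40, 3)
    for (p in pos) bvec[p] <- sample(setdiff(aa, bvec[p]), 1)
    b <- paste(bvec, collapse = "")
    expect_equal(pairwise_identity(a, b), 100 * 37 / 40)
  }
})

test_that("identity matrix is symmetric with unit diagonal", {
  set.seed(33)
  fam <- make_target_family_chains(6, 2, seed = 33)
  m <- identity_matrix(fam$chains)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(100, 6))
  expect_true(all(m >= 0 & m <= 100))
})

test_that("single-linkage semantics: full linkage and transitivity", {
  seqs <- rep(strrep("ACDKW", 8), 3)
  chains <- data.frame(key = c("S1_A", "S2_A", "S3_A"), sequence = seqs)
  cl <- cluster_targets(chains)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$members, c("S1_A", "S2_A", "S3_A"))

  # transitive merging via a precomputed identity matrix: A-B 40, B-C 40,
  # A-C 10 at threshold 35 gives one component
  keys <- c("A", "B", "C")
  m <- matrix(c(100, 40, 10, 40, 100, 40, 10, 40, 100), 3,
              dimnames = list(keys, keys))
  chains <- data.frame(key = keys, sequence = c("AAAA", "CCCC", "DDDD"))
  cl <- cluster_targets(chains, threshold = 35, identity = m)
  expect_equal(length(cl), 1L)

  # identity exactly at the threshold is redundant (linked)
  m2 <- matrix(c(100, 35, 35, 100), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  cl2 <- cluster_targets(data.frame(key = c("A", "B"),
                                    sequence = c("AAAA", "CCCC")),
                         threshold = 35, identity = m2)
  expect_equal(length(cl2), 1L)
})

test_that("representative is the longest member with lexicographic ties", {
  chains <- data.frame(
    key = c("S2_A", "S1_A", "S3_A"),
    sequence = c(strrep("ACDKW", 8), strrep("ACDKW", 8),
                 paste0(strrep("ACDKW", 8), "ACD")))
  cl <- cluster_targets(chains)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$representative, "S3_A")  # longest wins
  chains$sequence[3] <- strrep("ACDKW", 8)
  cl <- cluster_targets(chains)
  expect_equal(cl[[1]]$representative, "S1_A")  # tie -> smallest key
})

test_that("cluster count is monotone in threshold and order-independent", {
  fam <- make_target_family_chains(12, 3, seed = 34)
  m <- identity_matrix(fam$chains)
  counts <- vapply(c(5, 35, 80, 99), function(th) {
    length(cluster_targets(fam$chains, threshold = th, identity = m))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  ref <- cluster_targets(fam$chains, identity = m)
  set.seed(35)
  for (k in 1:10) {
    perm <- sample(nrow(fam$chains))
    out <- cluster_targets(fam$chains[perm, ], identity = m)
    expect_identical(out, ref)
  }
})

test_that("nonredundant target count honors the filtration switch", {
  fam <- make_target_family_chains(5, 2, seed = 36)  # families of 3 and 2
  expect_equal(nonredundant_target_count(fam$chains), 2L)
  expect_equal(nonredundant_target_count(fam$chains,
                                         filtration_enabled = FALSE), 5L)
  one <- fam$chains[1, , drop = FALSE]
  expect_equal(nonredundant_target_count(one), 1L)
  expect_equal(nonredundant_target_count(one, filtration_enabled = FALSE), 1L)
})

test_that("TSV exports are well-formed", {
  fam <- make_target_family_chains(4, 2, seed = 37)
  m <- identity_matrix(fam$chains)
  tsv <- write_identity_tsv(m)
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 5L)
  cl <- cluster_targets(fam$chains, identity = m)
  ctsv <- write_cluster_tsv(cl)
  expect_equal(length(strsplit(ctsv, "\n")[[1]]), 5L)
})
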