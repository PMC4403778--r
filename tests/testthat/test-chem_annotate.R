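# Chemical annotation: bond perception, molecular weight, rule-of-five
# descriptors, path fingerprints, Tanimoto search and SMILES writing.

test_that("bond perception follows covalent distance with 0.45 A slack", {
  two_c <- function(d) data.frame(element = c("C", "C"),
                                  x = c(0, d), y = 0, z = 0)
  expect_equal(nrow(perceive_bonds(two_c(1.54))$bonds), 1L)
  expect_equal(nrow(perceive_bonds(two_c(3.0))$bonds), 0L)
  expect_error(perceive_bonds(data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unknown element")

  # ideal benzene ring: 6 bonds, one cycle, single fragment
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  benz <- data.frame(element = "C", x = 1.39 * cos(th), y = 1.39 * sin(th),
                     z = 0)
  g <- perceive_bonds(benz)
  expect_equal(nrow(g$bonds), 6L)
  expect_equal(g$n_fragments, 1L)
  deg <- table(factor(c(g$bonds[, 1], g$bonds[, 2]), levels = 1:6))
  expect_true(all(deg == 2))  # a single cycle

  # hydrogens bond only to their nearest heavy atom
  set.seed(51)
  atoms <- make_ligand_coords(10, n_h = 5)
  g2 <- perceive_bonds(atoms)
  expect_equal(nrow(g2$bonds), 9L + 5L)  # chain + one bond per H
})

test_that("perceived topology matches the generator's declared chain", {
  set.seed(52)
  for (k in 1:15) {
    n <- sample(5:16, 1)
    g <- perceive_bonds(make_ligand_coords(n))
    expect_equal(nrow(g$bonds), n - 1L)
    expect_equal(g$n_fragments, 1L)
    deg <- table(factor(c(g$bonds[, 1], g$bonds[, 2]), levels = seq_len(n)))
    expect_true(all(deg <= 2))  # simple path
  }
})

test_that("molecular weight equals the formula-summation oracle", {
  expect_equal(molecular_weight(molecular_graph("C", matrix(ncol = 2, nrow = 0))),
               12.011)
  set.seed(53)
  for (k in 1:10) {
    els <- sample(c("C", "N", "O", "S", "P", "H"), sample(3:20, 1), TRUE)
    g <- molecular_graph(els, matrix(ncol = 2, nrow = 0))
    expect_equal(molecular_weight(g), oracle_formula_weight(els),
                 tolerance = 0.01)
  }
})

test_that("lipinski: forced violations, hydrogen handling, monotonicity", {
  # MW 600 (50 carbons) with 6 N-H donors -> 2 violations
  els <- c(rep("C", 46), rep("N", 6), rep("H", 6))
  bonds <- rbind(cbind(1:51, 2:52), cbind(47:52, 53:58))
  g <- molecular_graph(els, bonds)
  d <- lipinski(g)
  expect_gt(d$molecular_weight, 500)
  expect_equal(d$hbd, 6L)
  expect_equal(d$hba, 6L)
  expect_equal(d$lipinski_violations, 2L)
  expect_false(d$druglike)
  expect_true(is.na(d$logp))

  # all-carbon graph: no donors or acceptors
  g2 <- molecular_graph(rep("C", 10), cbind(1:9, 2:10))
  d2 <- lipinski(g2)
  expect_equal(d2$hbd, 0L)
  expect_equal(d2$hba, 0L)
  expect_true(d2$druglike)

  # implicit-H imputation: terminal O on a chain has one donor H
  g3 <- molecular_graph(c("C", "C", "O"), cbind(1:2, 2:3))
  expect_equal(lipinski(g3)$hbd, 1L)
  expect_equal(lipinski(g3)$hba, 1L)
  # ether O (degree 2) donates nothing
  g4 <- molecular_graph(c("C", "O", "C"), cbind(1:2, 2:3))
  expect_equal(lipinski(g4)$hbd, 0L)

  # logp provider: >5 adds a violation
  expect_equal(lipinski(g2, logp = 6.2)$lipinski_violations, 1L)
  expect_equal(lipinski(g2, logp = 2.0)$lipinski_violations, 0L)

  # adding mass above 500 can only increase the violation count
  light <- lipinski(molecular_graph(rep("C", 10), cbind(1:9, 2:10)))
  heavy <- lipinski(molecular_graph(rep("C", 60), cbind(1:59, 2:60)))
  expect_gte(heavy$lipinski_violations, light$lipinski_violations)
})

test_that("path enumeration matches exhaustive expectations on tiny graphs", {
  g <- molecular_graph(c("C", "N", "O"), cbind(1:2, 2:3))
  expect_equal(enumerate_paths(g), sort(c("C", "N", "O", "C-N", "N-O",
                                          "C-N-O")))
  fp <- path_fingerprint(g)
  expect_lte(fp$n_set, 6L)
  expect_gte(fp$n_set, 1L)

  single <- molecular_graph("O", matrix(ncol = 2, nrow = 0))
  fps <- path_fingerprint(single)
  expect_equal(fps$n_set, 1L)
  expect_equal(enumerate_paths(single), "O")

  # canonicalization: a path and its reverse encode identically
  g_rev <- molecular_graph(c("O", "N", "C"), cbind(1:2, 2:3))
  expect_identical(enumerate_paths(g_rev), enumerate_paths(g))
})

test_that("fingerprints are invariant under atom reindexing", {
  set.seed(54)
  for (k in 1:8) {
    atoms <- make_ligand_coords(sample(8:14, 1))
    g <- perceive_bonds(atoms)
    fp <- path_fingerprint(g)
    for (shuffle in 1:10) {
      perm <- sample(nrow(atoms))
      atoms2 <- atoms[perm, , drop = FALSE]
      fp2 <- path_fingerprint(perceive_bonds(atoms2))
      expect_identical(fp2$bits, fp$bits)
    }
  }
})

test_that("tanimoto: identities, bounds, boundary cases", {
  mkfp <- function(bits) structure(list(bits = as.integer(bits),
                                        n_bits = 1024L,
                                        n_set = length(bits)),
                                   class = "fingerprint")
  expect_equal(tanimoto(mkfp(c(1, 5, 9)), mkfp(c(1, 5, 9))), 1.0)
  expect_equal(tanimoto(mkfp(1:3), mkfp(4:6)), 0.0)
  expect_equal(tanimoto(mkfp(1:3), mkfp(2:4)), 0.5)
  expect_equal(tanimoto(mkfp(integer(0)), mkfp(integer(0))), 1.0)
  expect_error(tanimoto(mkfp(1), structure(list(bits = 1L, n_bits = 512L),
                                           class = "fingerprint")),
               "mismatch")
  set.seed(55)
  for (k in 1:20) {
    a <- mkfp(sample(1024, sample(1:40, 1)))
    b <- mkfp(sample(1024, sample(1:40, 1)))
    t_ab <- tanimoto(a, b)
    expect_gte(t_ab, 0); expect_lte(t_ab, 1)
    expect_equal(tanimoto(b, a), t_ab)
    expect_equal(tanimoto(a, a), 1.0)
  }
})

test_that("similarity search ranks self-hits first and shrinks with cutoff", {
  set.seed(56)
  graphs <- lapply(1:6, function(i) perceive_bonds(make_ligand_coords(8 + i)))
  records <- lapply(seq_along(graphs), function(i) {
    list(component_id = sprintf("L%02d", i),
         fingerprint = path_fingerprint(graphs[[i]]))
  })
  hits <- similarity_search(graphs[[3]], records, cutoff = 0.0)
  expect_equal(nrow(hits), 6L)
  expect_equal(hits$component_id[1], "L03")
  expect_equal(hits$tanimoto[1], 1.0)
  expect_true(all(diff(hits$tanimoto) <= 0))

  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(ct) {
    nrow(similarity_search(graphs[[3]], records, cutoff = ct))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  none <- similarity_search(perceive_bonds(make_ligand_coords(20,
                                                              elements = "S")),
                            records, cutoff = 1.0)
  expect_equal(nrow(none), 0L)
})

test_that("SMILES writing covers atoms, chains, rings and fragments", {
  expect_equal(to_smiles(molecular_graph("O", matrix(ncol = 2, nrow = 0))),
               "[O]")
  cco <- to_smiles(molecular_graph(c("C", "C", "O"), cbind(1:2, 2:3)))
  g_back <- mtlminer:::parse_smiles_graph(cco)
  expect_equal(nrow(g_back$atoms), 3L)
  expect_equal(nrow(g_back$bonds), 2L)

  # ring closure survives the round trip
  ring <- molecular_graph(rep("C", 6), rbind(cbind(1:5, 2:6), c(1, 6)))
  g_ring <- mtlminer:::parse_smiles_graph(to_smiles(ring))
  expect_equal(nrow(g_ring$bonds), 6L)

  # disconnected graphs are dot-separated
  frag <- molecular_graph(c("C", "C", "O"), matrix(c(1, 2), ncol = 2))
  sm <- to_smiles(frag)
  expect_match(sm, ".", fixed = TRUE)
  g_frag <- mtlminer:::parse_smiles_graph(sm)
  expect_equal(nrow(g_frag$atoms), 3L)
  expect_equal(nrow(g_frag$bonds), 1L)

  # random graphs: atom/bond counts preserved through write/parse
  set.seed(57)
  for (k in 1:20) {
    g <- perceive_bonds(make_ligand_coords(sample(5:15, 1)))
    heavy_bonds <- nrow(g$bonds)
    back <- mtlminer:::parse_smiles_graph(to_smiles(g))
    expect_equal(nrow(back$atoms), nrow(g$atoms))
    expect_equal(nrow(back$bonds), heavy_bonds)
    expect_equal(sort(back$atoms$element), sort(g$atoms$element))
  }
})

test_that("descriptor TSV and fingerprint hex exports are well-formed", {
  g <- molecular_graph(c("C", "N", "O"), cbind(1:2, 2:3))
  rec <- list(list(component_id = "LG1", descriptors = lipinski(g),
                   fingerprint = path_fingerprint(g)))
  tsv <- write_descriptor_tsv(rec)
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 2L)
  hex <- fingerprint_hex(rec[[1]]$fingerprint)
  expect_equal(nchar(hex), 256L)
  expect_match(hex, "^[0-9a-f]+$")
})
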