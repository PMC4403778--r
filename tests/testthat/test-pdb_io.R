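# PDB parsing/writing: fixed-column semantics, first-model rule, quality
# gate boundaries, chain sequences, write round-trips.

min_pdb <- c(
  "ATOM      1  CA  ALA A   1      11.000   2.000   3.000  1.00  0.00           C",
  "HETATM    2  C1  LIG X   1       1.000   2.000   3.000  1.00  0.00           C",
  "END")

test_that("minimal parse yields one polymer and one hetero atom", {
  s <- parse_structure(min_pdb, structure_id = "TEST")
  expect_s3_class(s, "mtld_structure")
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$record, c("polymer", "hetero"))
  expect_equal(s$atoms$element, c("C", "C"))
  expect_true(all(is.finite(s$atoms$x)))
})

test_that("resolution, method and header are read from their records", {
  txt <- c("HEADER    TEST PROTEIN                            01-JAN-13   1ABC",
           "EXPDTA    X-RAY DIFFRACTION",
           "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
           min_pdb)
  s <- parse_structure(txt)
  expect_equal(s$resolution, 1.80)
  expect_equal(s$experiment_method, "X-RAY DIFFRACTION")
  expect_equal(s$structure_id, "1ABC")
  # absent resolution stays absent
  expect_true(is.na(parse_structure(min_pdb)$resolution))
})

test_that("only the first MODEL contributes atoms", {
  block <- function(z) {
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:10, 1:10, 1:10 * 2, 0, z)
  }
  txt <- c("MODEL        1", block(0), "ENDMDL",
           "MODEL        2", block(9), "ENDMDL", "END")
  s <- parse_structure(txt)
  expect_equal(nrow(s$atoms), 10L)
  expect_equal(s$model_count, 2L)
  expect_true(all(s$atoms$z == 0))
})

test_that("malformed coordinate lines are skipped with a warning, not fatal", {
  txt <- c(min_pdb[1],
           "ATOM      2  CB  ALA A   1      xx.xxx   2.000   3.000  1.00  0.00           C",
           min_pdb[2:3])
  expect_warning(s <- parse_structure(txt), "malformed")
  expect_equal(nrow(s$atoms), 2L)
  expect_error(parse_structure(c("REMARK nothing", "END")), "empty")
})

test_that("structure filter: strict resolution bound and method gate", {
  mk <- function(res, method) {
    structure(list(structure_id = "XXXX", experiment_method = method,
                   resolution = res, atoms = NULL, model_count = 1L),
              class = "mtld_structure")
  }
  expect_true(passes_structure_filter(mk(2.5, "X-RAY DIFFRACTION")))
  expect_false(passes_structure_filter(mk(3.0, "X-RAY DIFFRACTION")))
  expect_false(passes_structure_filter(mk(1.2, "SOLUTION NMR")))
  expect_true(passes_structure_filter(mk(1.2, "SOLUTION NMR"),
                                      require_xray = FALSE))
  expect_false(passes_structure_filter(mk(NA_real_, "X-RAY DIFFRACTION")))
  # monotonicity: passing at r implies passing at every larger bound
  s <- mk(2.99, "X-RAY DIFFRACTION")
  expect_true(passes_structure_filter(s, 3.0))
  for (r in c(3.5, 4, 10)) expect_true(passes_structure_filter(s, r))
})

test_that("chain sequences: mapping rule, ligand-only chains, round-trip", {
  txt <- c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  MSE A   3       8.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  LIG L   1      20.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_structure(txt)
  seqs <- chain_sequences(s)
  expect_equal(names(seqs), "A")
  expect_equal(seqs$A$sequence, "AGX")
  expect_equal(chain_sequences(s, mse_to_met = TRUE)$A$sequence, "AGM")
  expect_equal(nrow(seqs$A$residue_index_map), 3L)

  # fixture generator round-trip: a known 20-mer comes back verbatim
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  txt2 <- make_complex("T020", chains = list(list(chain_id = "A",
                                                  sequence = seq20)))
  s2 <- parse_structure(txt2)
  expect_equal(chain_sequences(s2)$A$sequence, seq20)
})

test_that("write_substructure round-trips and is byte-stable", {
  set.seed(42)
  txt <- make_complex("T001",
                      chains = list(list(chain_id = "A", sequence = "AG"),
                                    list(chain_id = "B", sequence = "VL")),
                      ligands = list(list(component_id = "LG1",
                                          atoms = make_ligand_coords(12))))
  s <- parse_structure(txt)
  out <- write_substructure(s$atoms, header_comment = "round trip")
  s2 <- parse_structure(out)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$resseq, s$atoms$resseq)
  expect_equal(s2$atoms$resname, s$atoms$resname)
  expect_equal(s2$atoms$x, round(s$atoms$x, 3))
  expect_equal(s2$atoms$y, round(s$atoms$y, 3))
  expect_true(all(c("A", "B") %in% s2$atoms$chain))

  # determinism harness over random substructures
  for (k in 1:25) {
    idx <- sample(nrow(s$atoms), sample(3:nrow(s$atoms), 1))
    sub <- s$atoms[idx, , drop = FALSE]
    expect_identical(write_substructure(sub), write_substructure(sub))
  }
  expect_error(write_substructure(s$atoms[0, ]), "empty")
})

test_that("parsing is pure and FASTA export carries structure ids", {
  txt <- make_complex("T002", chains = list(list(chain_id = "A",
                                                 sequence = "AGAG")))
  expect_identical(parse_structure(txt), parse_structure(txt))
  s <- parse_structure(txt)
  fa <- write_chain_fasta(chain_sequences(s), s$structure_id)
  expect_match(fa, ">T002_A", fixed = TRUE)
  expect_match(fa, "AGAG", fixed = TRUE)
})
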