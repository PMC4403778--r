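Package: mtlminer
Title: Mining Multiple-Target Ligands from Protein-Ligand Crystal Structures
Version: 0.1.0
Authors@R:
    person("MTL", "Miner Developers", email = "mtlminer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for mining a corpus of protein-ligand crystal structures
    for multiple-target ligands (MTLs): parses legacy PDB coordinate files,
    extracts ligands by a heavy-atom threshold, computes binding sites as all
    protein residues within a cutoff radius of any ligand atom, collapses
    redundant targets by pairwise sequence identity (single-linkage clustering
    at a configurable threshold), quantifies ligand conformational variability
    across complexes by Kabsch superposition RMSD, and annotates ligands
    chemically (bond perception, molecular weight, Lipinski rule-of-five
    descriptors, path fingerprints with Tanimoto similarity search, and
    connectivity-level SMILES). Includes a synthetic-corpus generator with
    declared ground truth so every pipeline stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
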