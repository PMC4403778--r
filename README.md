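# mtlminer

Mining **multiple-target ligands (MTLs)** — small molecules observed in
crystal structures bound to two or more genuinely distinct proteins — from a
directory of legacy PDB coordinate files. Polypharmacology (one compound
acting on several targets) underlies both the efficacy and the side effects
of many drugs; crystallographic evidence of the same chemical component
sitting in binding sites of unrelated proteins is the most direct structural
signal of it. `mtlminer` re-implements that mining procedure as a reusable R
toolkit for structural bioinformaticians and cheminformaticians, with a
synthetic-corpus generator so that every stage is testable offline.

## The method

For a corpus of structures the pipeline applies, in order:

1. **Structure quality gate** — keep X-ray structures with resolution
   *r* < 3.0 Å (strict; structures without a parseable resolution never pass).
2. **Ligand extraction** — each hetero residue with **> 8 heavy atoms**
   (non-H, non-D; strict) becomes a ligand instance; water is always excluded.
3. **Binding-site extraction** — the site of a ligand is the set of protein
   residues with any atom within **6.0 Å** (inclusive) of any ligand atom;
   sites with **> 5 residues** (strict) qualify. Member residues contribute
   all their atoms.
4. **Multi-structure gate** — keep components observed in ≥ 2 distinct
   structures.
5. **Redundancy filtration** — the primary binding chain of each complex
   (the chain contributing most site residues) is aligned globally
   (BLOSUM62, gap open 10, gap extend 0.5) against the others; percent
   identity is `100 · identical positions / shorter length`. Chains with
   identity **≥ 35 %** are linked and single-linkage connected components
   form the non-redundant target clusters. A ligand is an **MTL** iff its
   cluster count is ≥ 2. The filtration can be switched off to recover the
   full chain list.
6. **Conformational analysis** — conformers of one component are matched by
   atom name and superposed with the Kabsch algorithm (proper rotations
   only); the **maximal pairwise RMSD** classifies the ligand as *rigid*
   (≤ 2.0 Å, inclusive) or *flexible*.
7. **Chemical annotation** — covalent-distance bond perception, molecular
   weight, Lipinski rule-of-five descriptors (drug-like = at most one
   violation of MW ≤ 500, H-bond donors ≤ 5, acceptors ≤ 10, logP ≤ 5 when
   a logP provider is supplied), an FP2-style 1024-bit path fingerprint
   (linear heavy-atom paths of up to 7 atoms) with Tanimoto similarity
   search (default cutoff 0.8), and connectivity-level SMILES.

Statistics mirror the usual reporting: target-count bins (2 | 3–5 | 6–10 |
> 10), a 100-Da molecular-weight histogram, a 0.5-Å max-RMSD histogram with
the rigid fraction, and the drug-like fraction.

## Worked example

```r
library(mtlminer)

spec  <- random_corpus_spec(42)          # seeded synthetic corpus plan
truth <- make_corpus(spec, "demo42")     # writes PDB files + truth.json
db    <- run_pipeline("demo42", pipeline_config(), verbose = TRUE)
#> structures passing quality gate: 6
#> ligand instances: 6; qualifying sites: 6
#> components in >=2 structures: 2
#> MTL records: 1 of 2 candidates
db
#> <mtld_database> 2 record(s), 1 MTL(s), 6 site(s) from 6 structure(s)

rec <- db$records[["L01"]]
rec$nonredundant_target_count   # 3  -> bound chains collapse to 3 targets
rec$is_mtl                      # TRUE
rec$smiles                      # "[C][C][C][N][O][C][C][C][N][O][C][C]"
rec$conformer_report
#> <conformer_report L01> 4 conformers, max RMSD 0.001, class rigid
db$stats$target_count_bins
#>    2  3-5 6-10  >10
#>    0    1    0    0

export_database(db, "demo42_out")  # ligand/site PDBs, SMILES, FASTA,
                                   # record JSON, stats, hashed manifest
```

The corpus here is synthetic: `L01` was planted to bind chains from three
unrelated sequence families, so three non-redundant targets come back; its
conformers are rigid copies, so the maximal RMSD is ~0 (the 0.001 Å residue
comes from the 3-decimal PDB coordinate precision).

A command-line wrapper is installed under `inst/scripts/mtlminer`:

```sh
mtlminer run --pdb-dir D --out O [--identity-threshold 35] [--no-identity-filtration]
mtlminer stats --db O
mtlminer search --db O --smiles '[C][C][O]' --cutoff 0.8
mtlminer fixtures --out D --seed 7
```

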