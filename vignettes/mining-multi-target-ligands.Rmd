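---
title: "Mining multiple-target ligands from crystal structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multiple-target ligands from crystal structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlminer)
```

## The problem

A *multiple-target ligand* (MTL) is a chemical component that has been
crystallized in complex with two or more proteins that remain distinct
after redundancy removal. Crystal structure archives are heavily redundant
— the same protein is solved dozens of times, often with the same ligand —
so a naive count of "proteins bound" wildly overstates promiscuity (a
steroid bound in 37 deposited complexes may in truth address only three
targets). `mtlminer` turns a directory of legacy PDB files into a database
of ligand records with non-redundant target counts, binding-site
structures, conformational-variability summaries and chemical annotations.

## Pipeline model and assumptions

The stages and their defaults (all held in `pipeline_config()`):

| stage | rule | default | strictness |
|---|---|---|---|
| structure gate | X-ray and resolution < `max_resolution` | 3.0 Å | strict `<` |
| ligand gate | heavy atoms > `min_heavy_atoms` | 8 | strict `>` |
| site definition | residue has any atom within `site_radius` of any ligand atom | 6.0 Å | inclusive `<=` |
| site gate | residues > `min_site_residues` | 5 | strict `>` |
| multi-structure gate | component in >= 2 distinct structures | 2 | — |
| redundancy | identity >= `identity_threshold` links chains | 35 % | `>=` links |
| flexibility | max pairwise RMSD <= `rmsd_class_cutoff` is rigid | 2.0 Å | inclusive |
| similarity search | Tanimoto >= `tanimoto_cutoff` | 0.8 | inclusive |

The strict/inclusive readings follow the mining criteria the pipeline
reproduces: the resolution, heavy-atom and site-size rules are stated as
strict inequalities, so their boundary values fail; "within a radius" is
read inclusively for the site, and a pair at exactly the identity threshold
is treated as redundant because only strictly-smaller identities are
retained. The multi-structure gate is applied *before* identity filtration,
and two copies of a ligand inside one structure count as one structure.

Assumptions worth making explicit:

* Only the first MODEL of a multi-model file is read (X-ray focus makes
  extra models rare); alternate locations other than blank/"A" are dropped.
* Sequences are derived from ATOM records, not SEQRES or external
  databases; unknown three-letter codes map to `X`, with an opt-in
  MSE-to-M mapping.
* Sites are restricted to amino-acid polymer residues; nucleic-acid
  contacts are out of scope.
* A multi-chain site is attributed to one *primary binding chain* — the
  chain contributing most site residues, ties broken alphabetically — for
  target-identity purposes.
* Ligands are keyed by chemical component id; covalently linked
  multi-residue entities are not merged.

## Sequence identity and clustering

Percent identity is computed from a global, end-gap-penalized alignment
(BLOSUM62, gap opening 10, gap extension 0.5; `Biostrings::pairwiseAlignment`
supplies the dynamic programming, and the test suite checks it against an
independently written Gotoh implementation). The denominator is the
*shorter* sequence length — the common culling convention — and is
configurable to alignment length. The mining procedure this reproduces did
not publish its identity algorithm, denominator or linkage; these choices
are declared package decisions, not reconstructions.

Clustering is single linkage over the "identity >= threshold" relation:
deterministic, order-independent, and faithful to the set-level statement
that all retained pairs fall below the threshold. Single linkage can merge
two chains whose direct identity is below the threshold through a chain of
intermediates; we accept this (it only ever makes the target count more
conservative). The cluster representative is the longest member, ties
broken by smallest key, so exports are stable.

## Superposition and the flexibility criterion

Conformers of a component are matched *by atom name* over heavy atoms;
graph-automorphism symmetry (e.g. two equivalent phenyl carbons swapped in
deposition) is not searched, which can only bias RMSD upward — a documented
caveat. Fewer than three shared names makes the problem under-determined
and the pair is recorded as unmatchable; a component with no matchable pair
is classified `undetermined`.

The superposition is the closed-form Kabsch solution with the determinant
correction, so mirror images never superpose to zero. The maximal entry of
the pairwise RMSD matrix is the flexibility criterion; the rigid/flexible
cutoff is *inclusive* at 2.0 Å, following the figure-caption reading
("<= 2 Å") over the slightly different prose wording — recorded here
because the two sources disagree at the boundary.

## Chemical annotation choices

Bonds are perceived from coordinates: two heavy atoms bond iff their
distance is at most the sum of covalent radii plus 0.45 Å (common
perception practice; configurable), and a hydrogen bonds only to its
nearest heavy atom. Bond *orders* are deliberately not perceived: the
fingerprint is therefore an **FP2-style** path fingerprint — all linear
heavy-atom paths of 1..7 atoms, canonicalized as the lexicographic minimum
of forward/reverse element strings, hashed into 1024 bits with a fixed,
versioned polynomial hash (`poly31-v1`, recorded in every export) — not a
bit-compatible Open Babel FP2. Reproducing the original web server's exact
hit lists is a non-goal; Tanimoto ranking behaviour (bounds, symmetry,
monotone cutoff) is what the tests pin down.

Rule-of-five descriptors: donors are O–H/N–H bonds (counted from explicit
hydrogens when present, otherwise imputed as `max(0, default valence −
heavy degree)` for N and O — the same convention an implicit-hydrogen
toolkit uses); acceptors are the N+O count; logP comes from a pluggable
provider and the logP criterion is *skipped, never guessed*, when no
provider is given (the original used a proprietary descriptor module that
is out of scope). Drug-like means at most one violation. SMILES output is
connectivity-level with bracket atoms: parseable by any standard reader and
round-trip-stable in element multiset and bond count, but carrying no bond
orders, aromaticity or stereochemistry.

## What the synthetic corpora emulate — and what they do not

`random_corpus_spec()` + `make_corpus()` generate corpora in which every
quantity the pipeline is supposed to recover is *planted*:

* **Contact distances.** A contact residue's CA is placed on a ray through
  the extremal ligand atom in that direction, at exactly the requested
  nearest-atom distance (provably the minimum over all ligand atoms);
  backbone atoms sit strictly farther out. Site membership is therefore
  known exactly, up to the 3-decimal PDB coordinate precision (~0.002 Å,
  which is why planted distances keep a safety margin around the 6.0 Å
  radius).
* **Sequence families.** Families use disjoint residue alphabets
  (between-family identity exactly 0) and members mutate 5 % of positions
  within the family alphabet (identity ~95 %), so cluster counts are
  deterministic truths rather than probabilistic ones.
* **Conformer RMSDs.** One conformer per component is displaced along a
  direction orthogonal to the rigid-motion subspace and rescaled by
  bisection until the measured optimal-superposition RMSD equals the
  planted value; all other conformers are rigid copies, so the component's
  true maximal pairwise RMSD *is* the planted value.
* Decoys: waters, sub-threshold hetero groups, single-structure components
  and structures failing the resolution gate.

Chains are CA/N/C/O pseudo-residues on rays and anchors — not plausible
protein geometry. A green end-to-end test therefore establishes that the
pipeline's *logic* (gates, aggregation, clustering, superposition,
bookkeeping) is correct against declared truth; it says nothing about
robustness to real-world PDB pathologies (altloc soup, chain breaks,
microheterogeneity, nucleic-acid sites), and corpus-scale headline counts
of the original database are not reproducible at this scale by design.

## Numerical and determinism notes

* Distances use exact Euclidean comparisons (`<=` at the radius); the
  brute-force all-pairs oracle in the tests must agree *exactly*, so the
  vectorized implementation avoids any reordering that could change
  floating-point results.
* All orderings (records, residues, cluster members, export files) are
  radix-sorted on stable keys; exports are written with fixed formats and
  hashed into a manifest — two runs over the same directory are
  byte-identical.
* Randomness exists only in the fixture generator and flows from a single
  seed; the same spec always materializes the same corpus bytes.
* Degenerate inputs: empty sites are values, not errors; a structure with
  no parseable resolution fails the gate rather than being guessed; an
  unknown element symbol is an error in bond perception but counted (with
  a warning) as heavy in the ligand gate, so odd deposits are not silently
  dropped.

## Known limitations

* No mmCIF input; legacy PDB text only.
* Name-based atom matching biases conformer RMSD upward for symmetric
  ligands.
* The fingerprint is FP2-style, not FP2-identical; similarity hit lists
  will differ from tools that encode bond orders.
* Identity at 35 % with single linkage can over-merge through intermediate
  chains; target counts are conservative.
* The logP criterion of the rule of five is only evaluated when the caller
  supplies values.
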