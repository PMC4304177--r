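# pdbkernel

Curation toolkit for protein chains stored in legacy-format PDB files,
aimed at structural bioinformaticians who need clean, non-redundant,
consistently numbered chain sets for structure prediction, template
libraries and large-scale analysis.

Raw PDB entries are hard to use automatically: the deposited (SEQRES)
sequence disagrees with the coordinate (ATOM) records wherever electron
density was unresolved, modified residues hide behind non-standard
3-letter codes, alternate conformations duplicate atoms, author
numbering is arbitrary, and the archive is highly redundant.
`pdbkernel` provides:

* **Cleaning** — reference/coordinate reconciliation by a global
  alignment with gaps forbidden in the reference (match +1, mismatch 0,
  gap-in-coordinate −0.5, deterministic leftmost optimum), MODRES-based
  restoration of modified residue codes, pruning of atoms beyond each
  residue's standard heavy-atom composition, first-conformation altLoc
  selection, re-indexing from one, and quality filters (CA-only /
  length < 30 / more than 10% unknown residues).
* **Redundancy reduction** — pairwise similarity defined as
  local-alignment identities divided by the average sequence length,
  greedy clustering at the seven identity levels 0.90–0.30, and
  representative selection by sequence length (10-residue window),
  crystallographic resolution (X-ray before NMR), and deposit date.
* **Domain assignment** — a recursive SCOP-style protocol over pluggable
  sequence-search and structure-alignment backends: keep hits with
  E < 0.01 and Z > 4.5 (structure stage: Z > 4.5 alone), assign the
  best hit's `class.fold.superfamily.family` address, re-search
  unassigned regions longer than 30 residues, merge shorter ones into
  neighboring domains.
* **Missing-region modelling** — per-region candidate generation through
  a backend, an `rmsdRest ≤ 0.1 Å` filter that keeps the experimental
  structure intact, lowest-energy selection, and low-confidence flags
  for modelled regions of length ≥ 7.
* **Annotation** — 8→3-state secondary-structure reduction (H,G,I → H;
  E,B → E; rest → C) and relative solvent accessibility classes with
  strict breakpoints (exposed > 0.37, buried < 0.069).
* **Fixtures** — a synthetic legacy-PDB generator that plants defects
  with by-construction ground truth, so the whole stack is testable
  without downloading anything.

## Worked example

```r
library(pdbkernel)

# a synthetic chain: selenomethionine at position 5, residues 18-20
# missing from the coordinates
fx <- make_chain_fixture(strrep("ACDEFGHIKL", 4),
  defect_spec(missing_regions = data.frame(start = 18L, end = 20L),
              modres = data.frame(position = 5L, mod_code = "MSE",
                                  std_code = "MET")))
chain <- parse_pdb(fx$text)[[1]]
chain
#> <chain_record SYN1_A>
#>   method: XRAY  resolution: 2  deposited: 2006-12-05
#>   ref_seq (40 aa): ACDEXGHIKLACDEFGHIKLACDEFGHIKLACDEFGHIKL
#>   37 coordinate residues, 284 atoms
```

Position 5 reads `X` because SEQRES lists the modified code `MSE`.
Cleaning restores the coordinate residue to MET (the alignment anchors
the mismatch at position 5), prunes the selenium atom, finds the
missing region and re-indexes:

```r
res <- clean_chain(chain)
res$filter$kept
#> [1] TRUE
res$alignment$missing_regions
#>   start end
#> 1    18  20
res$alignment$mismatches
#> [1] 5
res$log$n_atoms_pruned
#> [1] 1
```

Model the missing region (stub generator, deterministic pseudo-energy)
and inspect the per-region report:

```r
out <- fill_chain(loop_task(res$chain, res$alignment$missing_regions,
                            n_candidates = 50), seed = 1)
out$report
#>   start end length n_generated n_after_filter selected_energy
#> 1    18  20      3          50             50    0.0007771833
#>   selected_rmsd_rest low_confidence
#> 1                  0          FALSE
```

All 50 candidates keep the experimental atoms untouched
(`selected_rmsd_rest` is 0), the lowest-pseudo-energy model is selected,
and a 3-residue interior loop is not flagged low-confidence (the flag
fires at length ≥ 7). Pairwise similarity follows the
identities-over-average-length definition exactly:

```r
pairwise_similarity(strrep("ACDEFGHIKL", 10), strrep("ACDEFGHIKL", 5))$value
#> [1] 0.6666667   # 50 identities / mean(100, 50)
```

A thin command-line front end wraps the same functions:

```sh
exec/pdbkernel clean in.pdb --out-dir cleaned --report report.tsv
exec/pdbkernel cluster --in seqs.fasta --level 90 --out clusters.tsv
```

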