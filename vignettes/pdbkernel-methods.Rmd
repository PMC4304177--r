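---
title: "Curating legacy PDB chains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating legacy PDB chains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbkernel)
```

# The problem

Legacy PDB files are an awkward substrate for automated analysis. The
deposited (SEQRES) sequence and the coordinate (ATOM) records frequently
disagree: residues without resolved electron density are simply absent
from the coordinates, chemically modified residues carry non-standard
names, alternate conformations duplicate atoms, and author residue
numbering is arbitrary. On top of that, the archive is massively
redundant at the sequence level. `pdbkernel` implements a curation stack
that turns raw legacy files into clean, consistently numbered chain
records; reduces redundancy to representative ("kernel") chains;
assigns SCOP-style domain addresses through pluggable search backends;
selects models for missing regions; and annotates chains with 3-state
secondary structure and solvent-accessibility classes.

# Chain cleaning

The pipeline applied by `clean_chain()` runs, in order:

1. **MODRES restoration** (`restore_modres`): every coordinate residue
   whose 3-letter code appears in the file's MODRES map and resolves to a
   standard residue is renamed to the standard code and flagged. On the
   reference side we deliberately leave SEQRES translation untouched: a
   modified code translates to `X`, and the alignment anchors the
   resulting reference/coordinate mismatch rather than hiding it.
2. **Alternate-conformation selection** (`select_altloc`): for every
   (residue, atom name) with several altLoc variants, the variant that
   occurs *first in file order* is kept. This is a literal reading of
   "first conformation"; it is not the lowest altLoc letter, although the
   two coincide in virtually all real files.
3. **Atom pruning** (`prune_atoms`): each residue keeps only the heavy
   atoms of its standard chemical composition (a built-in table for the
   20 amino acids; unknown residues keep the backbone). Hydrogens are
   always removed. The terminal carboxyl oxygen OXT is retained on the
   last coordinate residue only — the reference-final position can itself
   be missing, so "terminal" is defined on the coordinate chain.
4. **Reference/coordinate alignment** (`align_ref_coord`): a global
   alignment in which gaps are forbidden in the reference. Scoring is
   match +1, mismatch 0, gap-in-coordinate −0.5. Because the coordinate
   sequence threads completely into the reference, the number of gap
   columns is fixed at `len(ref) − len(coord)`; the scoring therefore
   reduces to maximizing matches, and a mismatch is always preferred over
   a gap pair. That property matters: restored modified residues (step 1)
   must stay mapped to their reference position even though the letters
   differ. Among equal-scoring alignments we return the lexicographically
   smallest placement (every aligned residue as far left as possible),
   computed by a suffix dynamic program followed by a greedy forward
   traceback, so results are fully deterministic. Unmapped reference
   intervals become the chain's *missing regions*.
5. **Re-indexing** (`reindex`): coordinate residues are renumbered by
   their mapped reference position, starting from one; insertion codes
   are cleared. Numbering gaps after re-indexing mark missing regions.
6. **Filters** (`apply_filters`): a chain is discarded when every residue
   has only a CA atom, when the reference sequence is shorter than 30
   residues (30 itself is kept), or when more than 10% of the reference
   letters are `X`. The 10% threshold is a package choice — the rule
   "too many unknown residues" needs a number — and is configurable via
   `clean_params()`.

Cleaning is idempotent, never moves or fabricates a coordinate, and the
cleaned chain is returned regardless of the filter verdict so that
callers can implement their own retention policy.

# Redundancy reduction

Pairwise similarity is the identity count of the best local alignment
divided by the average of the two sequence lengths. The built-in aligner
is `Biostrings::pairwiseAlignment` with an identity matrix (match +2,
mismatch −1, gap open −2, extend −1); the `aligner` argument accepts any
function with the same contract, so an external search engine can
substitute. A similarity of 1.0 therefore requires identical sequences,
and a 50-identity alignment between chains of lengths 100 and 50 scores
50/75 ≈ 0.667.

Clustering (`greedy_cluster`) is greedy and representative-based at the
seven identity levels 0.90–0.30: sequences are inserted in priority
order; each joins the first cluster whose representative it matches at
or above the level, otherwise it founds a new cluster. Priorities follow
the rule set: longer sequences first, but within a 10-residue window the
better (smaller) crystallographic resolution wins, X-ray always
outranking NMR, then the later deposit date, then the smaller chain id.
Two design points deserve a note:

* The *pairwise* priority rule is non-transitive (100 beats 91 by
  length-window logic, 91 beats 104 by resolution, 104 beats 100 …), so
  it cannot order a list by itself. Insertion uses a deterministic total
  order (length desc, effective resolution asc, date desc, id asc);
  cluster-level representative selection uses the *windowed* rule
  implemented in `select_representative()`: among members within 10
  residues of the maximum length, best resolution, then latest date,
  then smallest id. On any two-member set this coincides with the
  pairwise rule.
* "Higher resolution" means a numerically smaller Å value; NMR and other
  methods carry no usable resolution and rank after any X-ray entry.

`cluster_id_list()` restricts clustering to a user-supplied id list and
re-selects representatives among the listed members only.

# Domain assignment

`assign_domains()` implements a recursive classification protocol over
two backends: a sequence search (E-values) and a structure aligner
(Z-scores), both returning hits that carry a SCOP-style address
`class.fold.superfamily.family`. Gates are strict: a sequence-stage hit
must satisfy `E < 0.01` **and** `Z > 4.5`; the structure stage, consulted
only when the sequence stage yields nothing, requires `Z > 4.5` alone.
The best hit (highest Z, ties to longer target, then smaller id) assigns
its address over its query span. Each maximal unassigned interval longer
than 30 residues is re-searched as a subsequence (backend hits are
clipped and re-localized); intervals of length ≤ 30 are merged into a
neighboring domain — interior gaps go to the neighbor with the longer
adjacent segment, ties to the preceding one, terminal gaps to their only
neighbor. An interval in which neither backend finds a surviving hit is
permanently unassigned; combined with strictly shrinking intervals this
guarantees termination. The merge-neighbor choice is not dictated by the
protocol description and is our deterministic convention.

The ≥ 80% region-overlap criterion used to score multi-domain
predictions against a reference classification is provided as a separate
evaluation utility (`domain_overlap_correct`), not as part of
assignment, since it requires reference data the package does not ship.

# Missing-region modelling

`fill_chain()` runs, per missing region: generate `n_candidates`
(default 500) full-chain candidates through the generator backend;
compute `rmsd_rest`, the RMSD between candidate and experimental
structure over all heavy atoms *outside* the missing regions; discard
candidates with `rmsd_rest > 0.1` Å (exactly 0.1 survives); score the
survivors with the energy backend and keep the minimum (ties to the
earliest candidate). `rmsd_rest` is computed in the shared coordinate
frame *without* superposition: the generator is required to keep
non-loop atoms near their experimental positions, and superposing first
would mask precisely the drift the 0.1 Å filter exists to catch. The
candidate budget is interpreted per region; regions are treated
independently.

Modelled regions of length ≥ 7 are flagged low-confidence, reflecting
the observation that loop-modelling quality degrades sharply beyond six
residues; terminal regions are always flagged, as chain termini are
usually disordered.

The built-in `stub_generator` places backbone atoms by linear
interpolation between the anchoring CA positions (linear extension at
termini) with seeded jitter, and `stub_scorer` returns a deterministic
CA-spacing strain pseudo-energy. Both exist so the selection protocol is
fully testable; neither claims physical realism, and both plug into the
same contracts an external modelling engine and statistical potential
would use.

# Annotation

`ss8_to_ss3()` reduces 8-state secondary structure with the conventional
mapping H,G,I → H; E,B → E; T,S,blank → C (the 3-state names are fixed;
the treatment of G/I/B/T/S is the standard reduction, chosen here).
`compute_rsa()` divides absolute accessibility by the residue-type
maximum from the Rost & Sander (1994) normalization table (configurable)
and clamps to [0, 1]. `classify_rsa()` is piecewise constant with two
strict breakpoints: exposed above 0.37, buried below 0.069, intermediate
in between — both boundary values are intermediate. `annotate_chain()`
aligns backend output to reference positions and marks positions without
coordinates (and residues without a normalization constant, i.e. `X`)
with `-`.

# Synthetic fixtures and what they do (and do not) show

`make_chain_fixture()` emits a legacy PDB file embodying a requested
defect list — missing regions, MODRES-restorable modified residues
(selenomethionine-style, carrying one atom beyond the parent
composition), altLoc variants, extra atoms, CA-only structures, unknown
residues, terminal OXT — over an idealized extended backbone, together
with by-construction ground truth. `make_clean_suite()` randomizes
defect specs and always includes the deterministic boundary cases
(length 29 vs 30, CA-only, X-rich).

Fixture sequences are drawn from a rotating 20-letter alphabet (a random
permutation repeated with period 20). Any alternative placement of a
coordinate residue shifts it to a reference position with a different
letter, so the planted alignment is provably the unique optimum and the
recorded ground truth is exact. Real proteins contain repeats and
low-complexity stretches for which several alignments can tie; the
alignment then still returns the deterministic leftmost optimum, but the
"true" gap position is genuinely ambiguous. Passing the fixture suite
therefore demonstrates correctness of the algorithm, not resolution of
intrinsically ambiguous real-world cases. Likewise the idealized
geometry means the suite exercises record-level cleaning logic, not
steric plausibility.

`make_family()` plants identity structure by copy-and-mutate from a
per-group base sequence at substitution rate `(1 − target)/2` per member
and verifies realized similarities with the built-in aligner (within ±3
percentage points inside groups; below a stated bound across groups).
Arbitrary pairwise identity-target matrices are not constructively
realizable, which is why the generator supports group-structured targets
only. `make_hit_script()` turns a global hit table into a backend that
clips and re-localizes hits for recursed subqueries.

# Numerical choices and degenerate inputs

* Alignment scores are multiples of 0.5 and exactly representable, so
  the traceback's equality tests are safe in floating point.
* Parse errors name the offending line; an empty or coordinate-free file
  is rejected; chains present only in SEQRES are skipped with a message;
  a chain with coordinates but no SEQRES gets its reference from the
  coordinates and is flagged.
* Deposit dates use the HEADER `dd-MMM-yy` field with pivot 71 (≥ 71 →
  19xx), consistent with the earliest depositions in the archive.
* Multi-model (NMR) files contribute only their first model.
* Coordinates are written at three decimals (the fixed-column format's
  precision); fixtures generate coordinates already rounded so that
  write/parse round trips are bit-exact.
* An empty candidate list after the rmsdRest filter is an error carrying
  the per-stage counts, not a silent fallback.

# Problem sizes used in the checks

The shipped verification suite runs at desk scale, chosen to exercise
every code path rather than to reproduce archive-scale statistics: 200
randomized fixture chains for the cleaning/round-trip properties,
exhaustive alignment cases to reference length 3 plus 10,000 randomized
pairs to length 12 against the enumeration oracle, 1,000 member sets for
the representative rule, 500 randomized scripted backends against the
protocol simulator, and a 10,000-point RSA grid. Archive-scale counts,
classification accuracy against curated SCOP releases, and loop-quality
benchmarks require external datasets and are out of scope.
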