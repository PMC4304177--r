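Package: pdbkernel
Title: Cleaning, Redundancy Reduction and Annotation of Legacy PDB Protein Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curation toolkit for protein-chain records stored in legacy
    PDB files. Parses fixed-column PDB records into chain-level objects,
    reconciles the SEQRES reference sequence with the coordinate-derived
    sequence under a no-gap-in-reference alignment, restores modified
    residue codes from MODRES records, prunes non-standard atoms, resolves
    alternate conformations, filters low-quality chains and re-indexes
    residues from one. Builds non-redundant chain sets by greedy clustering
    at seven sequence-identity levels with representative selection by
    length, resolution and deposit date. Assigns SCOP-style domain
    classifications through a recursive protocol over pluggable
    sequence-search and structure-alignment backends, selects models for
    missing regions by an RMSD-of-the-rest filter followed by lowest-energy
    selection, and annotates chains with 3-state secondary structure and
    relative solvent-accessibility classes. Includes a synthetic fixture
    generator so every stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
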