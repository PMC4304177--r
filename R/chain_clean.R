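# Chain cleaning: modified-residue restoration, atom pruning, alternate
# conformation selection, reference/coordinate sequence reconciliation,
# re-indexing and quality filters.

#' Cleaning parameters
#'
#' @param min_length minimum reference-sequence length kept (residues).
#'   A chain of exactly `min_length` residues is kept; shorter chains are
#'   removed.
#' @param max_x_fraction maximum tolerated fraction of `"X"` (unknown)
#'   letters in the reference sequence; chains strictly above it are
#'   removed.
#' @return a list of class `clean_params`. The alternate-conformation
#'   policy is fixed: the first conformation in file order is kept.
#' @export
clean_params <- function(min_length = 30L, max_x_fraction = 0.10) {
  stopifnot(min_length >= 1L, max_x_fraction > 0, max_x_fraction <= 1)
  structure(list(min_length = as.integer(min_length),
                 max_x_fraction = max_x_fraction, altloc_policy = "first"),
            class = "clean_params")
}

#' Restore modified residue codes via the file's MODRES map
#'
#' Every coordinate residue whose name appears in `modres_map` and maps to
#' a standard residue is renamed to the standard code and flagged
#' `is_modified`. Non-standard residues without a mapping are left as-is;
#' they contribute `"X"` to the coordinate-derived sequence.
#'
#' @param chain a [chain_record()].
#' @return the chain with restored residue names.
#' @export
restore_modres <- function(chain) {
  mm <- chain$modres_map
  if (length(mm)) {
    mm <- mm[mm %in% names(.AA_321)]  # only restore to standard residues
    hit <- chain$residues$res_name %in% names(mm)
    if (any(hit)) {
      chain$residues$res_name[hit] <- unname(mm[chain$residues$res_name[hit]])
      chain$residues$is_modified[hit] <- TRUE
    }
  }
  chain
}

#' Remove atoms beyond the standard amino-acid composition
#'
#' Each residue keeps only the heavy atoms belonging to the standard
#' chemical composition of its (restored) residue type; unknown residue
#' types keep the backbone. The terminal carboxyl oxygen `OXT` is retained
#' on the final coordinate residue only. Everything else, including
#' hydrogens, is removed.
#'
#' @param chain a [chain_record()], after [restore_modres()].
#' @return list-free: the chain with pruned atoms; the number of removed
#'   atoms is recorded in `attr(,"n_pruned")`.
#' @export
prune_atoms <- function(chain) {
  res <- chain$residues
  atoms <- chain$atoms
  allowed <- .AA_HEAVY_ATOMS[res$res_name]
  names(allowed) <- as.character(res$res_idx)
  allowed[vapply(allowed, is.null, logical(1))] <- list(.AA_HEAVY_ATOMS$UNK)
  last_idx <- res$res_idx[nrow(res)]
  keep <- vapply(seq_len(nrow(atoms)), function(i) {
    ri <- atoms$res_idx[i]
    nm <- atoms$name[i]
    nm %in% allowed[[as.character(ri)]] || (nm == "OXT" && ri == last_idx)
  }, logical(1))
  n_pruned <- sum(!keep)
  chain$atoms <- atoms[keep, , drop = FALSE]
  rownames(chain$atoms) <- NULL
  attr(chain, "n_pruned") <- n_pruned
  chain
}

#' Keep only the first conformation of alternate-location atoms
#'
#' For every (residue, atom name) with several alternate-location
#' variants, the variant occurring first in file order is kept and its
#' `alt_loc` field blanked.
#'
#' @param chain a [chain_record()].
#' @return the chain with a single conformation per atom; the number of
#'   discarded variants is in `attr(,"n_altloc_removed")`.
#' @export
select_altloc <- function(chain) {
  atoms <- chain$atoms
  key <- paste0(atoms$res_idx, "|", atoms$name)
  keep <- !duplicated(key)
  chain$atoms <- atoms[keep, , drop = FALSE]
  chain$atoms$alt_loc <- " "
  rownames(chain$atoms) <- NULL
  attr(chain, "n_altloc_removed") <- sum(!keep)
  chain
}

#' Align the coordinate sequence into the reference sequence
#'
#' Global alignment in which gap characters are permitted only in the
#' coordinate sequence: the coordinate residues are threaded into the
#' reference as an order-preserving (possibly mismatching) subsequence.
#' Scoring is match +1, mismatch 0, gap-in-coordinate -0.5; a gap in the
#' reference is forbidden. Among equal-scoring alignments the
#' lexicographically smallest placement (each aligned residue as far left
#' as possible) is returned, so results are deterministic.
#'
#' Mismatches are recorded and stay mapped -- a restored or modified
#' residue that no longer matches the reference letter is anchored at its
#' position rather than pushed into a gap.
#'
#' @param ref_seq reference 1-letter sequence (gaps forbidden).
#' @param coord_seq coordinate-derived 1-letter sequence; must not be
#'   longer than `ref_seq`.
#' @return a list of class `ref_coord_alignment` with elements `map`
#'   (integer vector: reference position of each coordinate residue),
#'   `missing_regions` (data.frame `start`,`end`, closed intervals of
#'   reference positions without coordinates), `mismatches` (reference
#'   positions where the aligned residue differs), `ref_len`, `n_matches`
#'   and `zero_match` (flagged inconsistency when nothing matches).
#' @export
align_ref_coord <- function(ref_seq, coord_seq) {
  r <- seq_to_letters(ref_seq)
  cs <- seq_to_letters(coord_seq)
  n <- length(r); m <- length(cs)
  if (n == 0L || m == 0L) stop("empty sequence in alignment")
  if (m > n) stop("alignment error: coordinate sequence longer than reference")
  gap <- -0.5
  # suffix DP: B[i, j] = best score of aligning coord[i..m] into the
  # reference columns j..n (j in 1..n+1; j = n+1 means no columns left)
  B <- matrix(-Inf, nrow = m + 1L, ncol = n + 2L)
  B[m + 1L, seq_len(n + 1L)] <- gap * (n - seq_len(n + 1L) + 1L)
  for (i in m:1) {
    js <- seq_len(n)
    diag_sc <- ifelse(cs[i] == r[js], 1, 0) + B[i + 1L, js + 1L]
    # placing residue i at column k >= j costs gap*(k-j) in between
    val <- diag_sc + gap * js
    best <- rev(cummax(rev(val)))
    B[i, js] <- best - gap * js
  }
  # forward traceback: greedily take the smallest feasible column, which
  # yields the lexicographically smallest optimal placement
  p <- integer(m)
  j <- 1L
  for (i in seq_len(m)) {
    k <- j
    repeat {
      sc <- (if (cs[i] == r[k]) 1 else 0) + B[i + 1L, k + 1L]
      if (gap * (k - j) + sc == B[i, j]) break
      k <- k + 1L
    }
    p[i] <- k
    j <- k + 1L
  }
  n_matches <- sum(cs == r[p])
  mism <- p[cs != r[p]]
  miss <- setdiff(seq_len(n), p)
  missing_regions <- intervals_from_positions(miss)
  structure(list(map = p, missing_regions = missing_regions,
                 mismatches = mism, ref_len = n, n_matches = n_matches,
                 zero_match = n_matches == 0L),
            class = "ref_coord_alignment")
}

#' @keywords internal
intervals_from_positions <- function(pos) {
  if (!length(pos)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1]])
}

#' Re-index coordinate residues by their reference positions
#'
#' Each coordinate residue's author numbering is replaced by its mapped
#' 1-based reference position; insertion codes are cleared. The first
#' mapped residue is therefore numbered from one, and residues after a
#' missing region keep the reference numbering (gaps in the numbers mark
#' the missing positions).
#'
#' @param chain a [chain_record()].
#' @param aln the [align_ref_coord()] result for this chain.
#' @return the re-indexed chain.
#' @export
reindex <- function(chain, aln) {
  stopifnot(length(aln$map) == nrow(chain$residues))
  chain$residues$res_num <- aln$map
  chain$residues$ins_code <- " "
  chain
}

#' Quality filters for cleaned chains
#'
#' A chain is removed when its structure has only CA atoms, when its
#' reference sequence is shorter than `min_length`, or when the fraction
#' of unknown (`"X"`) residues exceeds `max_x_fraction`.
#'
#' @param chain a cleaned [chain_record()].
#' @param params a [clean_params()] object.
#' @return a list of class `filter_report` with `kept` (flag) and
#'   `reasons` (subset of `CA_ONLY`, `TOO_SHORT`, `TOO_MANY_X`).
#' @export
apply_filters <- function(chain, params = clean_params()) {
  reasons <- character(0)
  nm_by_res <- split(chain$atoms$name, chain$atoms$res_idx)
  if (length(nm_by_res) &&
      all(vapply(nm_by_res, function(a) identical(unique(a), "CA"),
                 logical(1)))) {
    reasons <- c(reasons, "CA_ONLY")
  }
  if (nchar(chain$ref_seq) < params$min_length) {
    reasons <- c(reasons, "TOO_SHORT")
  }
  letters1 <- seq_to_letters(chain$ref_seq)
  if (mean(letters1 == "X") > params$max_x_fraction) {
    reasons <- c(reasons, "TOO_MANY_X")
  }
  structure(list(kept = length(reasons) == 0L, reasons = reasons),
            class = "filter_report")
}

#' Run the full cleaning pipeline on one chain
#'
#' Pipeline order: [restore_modres()], [select_altloc()], [prune_atoms()],
#' [align_ref_coord()], [reindex()], [apply_filters()]. The chain is
#' cleaned regardless of the filter verdict; the verdict is reported
#' separately so callers decide whether to keep it. The operation is
#' idempotent: cleaning a cleaned chain returns it unchanged.
#'
#' @param chain a parsed [chain_record()].
#' @param params a [clean_params()] object.
#' @return a list of class `clean_result` with elements `chain`
#'   (cleaned), `alignment` (a `ref_coord_alignment`), `filter` (a
#'   `filter_report`) and `log` (counts: `n_atoms_pruned`,
#'   `n_altloc_removed`, `restored_positions`).
#' @export
clean_chain <- function(chain, params = clean_params()) {
  ch <- restore_modres(chain)
  restored <- which(ch$residues$is_modified)
  ch <- select_altloc(ch)
  n_alt <- attr(ch, "n_altloc_removed")
  ch <- prune_atoms(ch)
  n_pruned <- attr(ch, "n_pruned")
  aln <- align_ref_coord(ch$ref_seq, coord_sequence(ch))
  ch <- reindex(ch, aln)
  rep_ <- apply_filters(ch, params)
  attr(ch, "n_pruned") <- NULL
  attr(ch, "n_altloc_removed") <- NULL
  structure(list(chain = ch, alignment = aln, filter = rep_,
                 log = list(n_atoms_pruned = n_pruned,
                            n_altloc_removed = n_alt,
                            restored_positions = restored)),
            class = "clean_result")
}
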