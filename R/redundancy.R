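# Non-redundant set generation: pairwise similarity as local-alignment
# identity over average length, greedy clustering at seven identity
# levels, and representative selection by length / resolution / date.

#' The seven supported identity levels
#' @export
CLUSTER_LEVELS <- c(0.90, 0.80, 0.70, 0.60, 0.50, 0.40, 0.30)

#' Built-in local-alignment backend
#'
#' Best single local alignment computed with
#' [Biostrings::pairwiseAlignment()] under an identity-matrix scoring
#' scheme (match +2, mismatch -1, gap open -2, gap extend -1). The
#' backend contract is a function `(a, b) -> list(identities, score)`, so
#' an external search tool can be plugged in instead.
#'
#' @param a,b 1-letter sequences.
#' @return list with `identities` (count of identical aligned positions;
#'   0 when no positive-scoring alignment exists) and `score`.
#' @export
biostrings_local_aligner <- function(a, b) {
  ab <- unique(c(seq_to_letters(a), seq_to_letters(b)))
  mat <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
  diag(mat) <- 2
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(list(identities = 0L, score = sc))
  list(identities = Biostrings::nmatch(aln), score = sc)
}

#' Pairwise sequence similarity
#'
#' Similarity between two sequences is the local-alignment identity count
#' divided by the average of the two sequence lengths:
#' `value = identities / ((len_a + len_b) / 2)`.
#'
#' @param a,b 1-letter sequences (non-empty).
#' @param aligner a local-alignment backend (default the built-in
#'   [biostrings_local_aligner()]).
#' @return list of class `similarity_score` with `identities`, `avg_len`
#'   and `value` in `[0, 1]`.
#' @export
pairwise_similarity <- function(a, b, aligner = biostrings_local_aligner) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence in pairwise_similarity")
  hit <- aligner(a, b)
  avg_len <- (nchar(a) + nchar(b)) / 2
  structure(list(identities = hit$identities, avg_len = avg_len,
                 value = hit$identities / avg_len),
            class = "similarity_score")
}

#' Priority key for representative selection
#'
#' @param id chain identifier (used as final deterministic tiebreak).
#' @param length sequence length in residues.
#' @param is_xray flag; X-ray structures always outrank NMR/other.
#' @param resolution Angstrom, or `NA`; ignored unless `is_xray`.
#' @param deposit_date a `Date`.
#' @return list of class `priority_key`.
#' @export
priority_key <- function(id, length, is_xray, resolution = NA_real_,
                         deposit_date = as.Date(NA)) {
  structure(list(id = id, length = as.integer(length),
                 is_xray = isTRUE(is_xray),
                 resolution = as.numeric(resolution),
                 deposit_date = as.Date(deposit_date)),
            class = "priority_key")
}

#' @keywords internal
effective_resolution <- function(key) {
  if (!key$is_xray || is.na(key$resolution)) Inf else key$resolution
}

#' Pairwise priority between two chains
#'
#' A longer sequence has higher priority, but when the length difference
#' is below 10 residues the better (numerically smaller) resolution wins;
#' X-ray always beats NMR/other, which carry no usable resolution. Ties
#' fall through to the later deposit date, and finally to the
#' lexicographically smaller chain id so the rule is total.
#'
#' @param a,b [priority_key()]s.
#' @return `"A"` or `"B"`, the higher-priority chain.
#' @export
rank_priority <- function(a, b) {
  if (abs(a$length - b$length) >= 10L) {
    return(if (a$length > b$length) "A" else "B")
  }
  ra <- effective_resolution(a); rb <- effective_resolution(b)
  if (ra != rb) return(if (ra < rb) "A" else "B")
  da <- a$deposit_date; db <- b$deposit_date
  if (!is.na(da) && !is.na(db) && da != db) {
    return(if (da > db) "A" else "B")
  }
  if (is.na(da) != is.na(db)) return(if (!is.na(da)) "A" else "B")
  if (identical(a$id, b$id) || a$id < b$id) "A" else "B"
}

#' Select the representative of a cluster
#'
#' Windowed form of the pairwise priority rule, which makes the choice a
#' total, deterministic function of the member set: let `L` be the
#' maximum member length; among members with length strictly greater than
#' `L - 10`, pick the best (smallest) resolution, then the latest deposit
#' date, then the smallest id. On any two-member set this agrees with
#' [rank_priority()].
#'
#' @param members non-empty list of [priority_key()]s.
#' @return the `id` of the selected member.
#' @export
select_representative <- function(members) {
  if (!length(members)) stop("empty cluster")
  len <- vapply(members, function(k) k$length, integer(1))
  L <- max(len)
  cand <- members[len > L - 10L]
  res <- vapply(cand, effective_resolution, numeric(1))
  cand <- cand[res == min(res)]
  dates <- vapply(cand, function(k) as.numeric(k$deposit_date), numeric(1))
  if (all(is.na(dates))) {
    dates <- rep(0, length(cand))
  } else {
    dates[is.na(dates)] <- -Inf
  }
  cand <- cand[dates == max(dates)]
  ids <- unname(vapply(cand, function(k) k$id, character(1)))
  ids[order(ids)][1]
}

# Deterministic total insertion order for greedy clustering: longest
# first, then best resolution, then latest date, then smallest id. This
# is the total-order surrogate for the (non-transitive) pairwise rule.
#' @keywords internal
priority_order <- function(keys) {
  len <- vapply(keys, function(k) k$length, integer(1))
  res <- vapply(keys, effective_resolution, numeric(1))
  dt <- vapply(keys, function(k) {
    d <- as.numeric(k$deposit_date); if (is.na(d)) -Inf else d
  }, numeric(1))
  ids <- vapply(keys, function(k) k$id, character(1))
  order(-len, res, -dt, ids)
}

#' Greedy clustering at one identity level
#'
#' Sequences are processed in descending priority order; each joins the
#' first existing cluster whose representative it matches at similarity
#' `>= level`, otherwise it founds a new cluster and becomes its
#' representative. Deterministic given the input.
#'
#' @param seqs named character vector of sequences (names are chain ids).
#' @param level one of the seven identity levels in [CLUSTER_LEVELS].
#' @param keys named list of [priority_key()]s (one per sequence); when
#'   omitted, keys are built from sequence lengths alone.
#' @param aligner local-alignment backend for [pairwise_similarity()].
#' @return a list of class `cluster_set` with `level` and `clusters`, a
#'   list of `list(representative, members)` (members include the
#'   representative).
#' @export
greedy_cluster <- function(seqs, level, keys = NULL,
                           aligner = biostrings_local_aligner) {
  if (!isTRUE(any(abs(level - CLUSTER_LEVELS) < 1e-9))) {
    stop("level must be one of ", paste(CLUSTER_LEVELS, collapse = ", "))
  }
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (is.null(keys)) {
    keys <- lapply(names(seqs), function(id) {
      priority_key(id, nchar(seqs[[id]]), is_xray = FALSE)
    })
    names(keys) <- names(seqs)
  }
  ord <- priority_order(keys[names(seqs)])
  ids <- names(seqs)[ord]
  reps <- character(0)
  members <- list()
  for (id in ids) {
    placed <- FALSE
    for (ri in seq_along(reps)) {
      sim <- pairwise_similarity(seqs[[id]], seqs[[reps[ri]]],
                                 aligner = aligner)$value
      if (sim >= level) {
        members[[ri]] <- c(members[[ri]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  clusters <- lapply(seq_along(reps), function(i) {
    list(representative = reps[i], members = members[[i]])
  })
  structure(list(level = level, clusters = clusters), class = "cluster_set")
}

#' Cluster a user-supplied list of chain ids
#'
#' Restriction of clustering to the listed chains: the greedy pass runs
#' over the listed sequences only and representatives are re-selected by
#' the windowed priority rule among the listed members of each cluster.
#'
#' @param ids character vector of chain ids.
#' @param level identity level.
#' @param store list with elements `seqs` (named character vector) and
#'   `keys` (named list of [priority_key()]s).
#' @param aligner local-alignment backend.
#' @return a `cluster_set` over the listed ids.
#' @export
cluster_id_list <- function(ids, level, store,
                            aligner = biostrings_local_aligner) {
  unknown <- setdiff(ids, names(store$seqs))
  if (length(unknown)) {
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  }
  cs <- greedy_cluster(store$seqs[ids], level, keys = store$keys[ids],
                       aligner = aligner)
  cs$clusters <- lapply(cs$clusters, function(cl) {
    cl$representative <- select_representative(store$keys[cl$members])
    cl
  })
  cs
}

#' Tabulate a cluster set
#'
#' @param cs a `cluster_set`.
#' @return data.frame with columns `level`, `representative`, `member`.
#' @export
cluster_table <- function(cs) {
  do.call(rbind, lapply(cs$clusters, function(cl) {
    data.frame(level = cs$level, representative = cl$representative,
               member = cl$members, stringsAsFactors = FALSE)
  }))
}
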