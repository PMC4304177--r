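# Recursive SCOP-style domain assignment over pluggable sequence-search
# and structure-alignment backends.
#
# A backend is a function (start, end) -> data.frame of hits for the
# query subsequence spanning the global interval [start, end]. Hits carry
# query-local coordinates (1 = `start`), a SCOP-style target address, an
# E-value and a structure-alignment Z-score.

UNASSIGNED <- "UNASSIGNED"

#' Assignment parameters
#'
#' @param e_max sequence-search E-value cutoff; hits must satisfy
#'   `e_value < e_max` (strict).
#' @param z_min structure-alignment Z-score cutoff; hits must satisfy
#'   `z_score > z_min` (strict).
#' @param min_recurse_len an unassigned region is re-searched only when
#'   strictly longer than this; a region of exactly this length is merged
#'   into a neighboring domain instead.
#' @return list of class `assign_params`.
#' @export
assign_params <- function(e_max = 0.01, z_min = 4.5, min_recurse_len = 30L) {
  stopifnot(e_max > 0, z_min > 0, min_recurse_len > 0)
  structure(list(e_max = e_max, z_min = z_min,
                 min_recurse_len = as.integer(min_recurse_len)),
            class = "assign_params")
}

#' @keywords internal
empty_hits <- function() {
  data.frame(target_id = character(0), target_address = character(0),
             e_value = numeric(0), z_score = numeric(0),
             query_start = integer(0), query_end = integer(0),
             target_len = integer(0), stringsAsFactors = FALSE)
}

#' Filter search hits by the stage thresholds
#'
#' At the sequence stage a hit must pass both tests: `e_value < e_max`
#' and `z_score > z_min`. At the structure stage only the Z-score test
#' applies (the E-value is ignored). Both inequalities are strict; input
#' order is preserved.
#'
#' @param hits data.frame of hits (may have zero rows).
#' @param params an [assign_params()].
#' @param stage `"SEQ"` or `"STRUCT"`.
#' @return the filtered data.frame.
#' @export
filter_hits <- function(hits, params = assign_params(),
                        stage = c("SEQ", "STRUCT")) {
  stage <- match.arg(stage)
  if (!nrow(hits)) return(hits)
  keep <- hits$z_score > params$z_min
  if (stage == "SEQ") keep <- keep & hits$e_value < params$e_max
  hits[keep, , drop = FALSE]
}

#' Pick the best hit
#'
#' Maximum Z-score; ties broken by larger target length, remaining ties
#' by smallest target id.
#'
#' @param hits non-empty data.frame of (already filtered) hits.
#' @return a one-row data.frame.
#' @export
pick_best_hit <- function(hits) {
  if (!nrow(hits)) stop("pick_best_hit: no hits (caller must handle the no-hit path)")
  ord <- order(-hits$z_score, -hits$target_len, hits$target_id)
  hits[ord[1], , drop = FALSE]
}

#' Assign SCOP-style domains to a query
#'
#' The recursive protocol: (i) query the sequence-search backend and keep
#' hits passing both the E-value and Z-score gates; (ii) if none survive,
#' query the structure-alignment backend against family representatives
#' and keep hits passing the Z-score gate; (iii) assign the best hit's
#' address over its query span; (iv) each maximal unassigned interval
#' strictly longer than `min_recurse_len` is re-searched as a
#' subsequence, shorter ones are left for merging; (v) short unassigned
#' regions are merged into neighboring domains. An interval in which
#' neither backend finds a hit stays unassigned permanently, which
#' together with the strictly shrinking intervals guarantees termination.
#'
#' @param query_len length of the query in residues.
#' @param seq_backend,struct_backend backend functions
#'   `(start, end) -> hits`; `struct_backend` may be `NULL`.
#' @param params an [assign_params()].
#' @param merge merge short unassigned regions at the end (default TRUE).
#' @return a list of class `domain_assignment` with `segments`
#'   (data.frame `start`, `end`, `address`; sorted, non-overlapping,
#'   covering `1..query_len`) and `query_len`.
#' @export
assign_domains <- function(query_len, seq_backend, struct_backend = NULL,
                           params = assign_params(), merge = TRUE) {
  query_len <- as.integer(query_len)
  stopifnot(query_len >= 1L)
  addr <- rep(NA_character_, query_len)

  run_backend <- function(backend, s, e, stage) {
    hits <- tryCatch(backend(s, e), error = function(err) {
      stop(sprintf("backend failure at stage %s on interval [%d, %d]: %s",
                   stage, s, e, conditionMessage(err)))
    })
    if (is.null(hits) || !nrow(hits)) return(empty_hits())
    filter_hits(hits, params, stage)
  }

  recurse <- function(s, e) {
    hits <- run_backend(seq_backend, s, e, "SEQ")
    if (!nrow(hits) && !is.null(struct_backend)) {
      hits <- run_backend(struct_backend, s, e, "STRUCT")
    }
    if (nrow(hits)) {
      # clip local spans to the current interval, drop emptied hits
      hits$query_start <- pmax(hits$query_start, 1L)
      hits$query_end <- pmin(hits$query_end, e - s + 1L)
      hits <- hits[hits$query_start <= hits$query_end, , drop = FALSE]
    }
    if (!nrow(hits)) {
      addr[s:e] <<- UNASSIGNED
      return(invisible(NULL))
    }
    best <- pick_best_hit(hits)
    gs <- s + best$query_start - 1L
    ge <- s + best$query_end - 1L
    addr[gs:ge] <<- best$target_address
    open <- intervals_from_positions((s:e)[is.na(addr[s:e])] )
    for (k in seq_len(nrow(open))) {
      os <- open$start[k]; oe <- open$end[k]
      if (oe - os + 1L > params$min_recurse_len) {
        recurse(os, oe)
      } else {
        addr[os:oe] <<- UNASSIGNED
      }
    }
    invisible(NULL)
  }

  recurse(1L, query_len)
  out <- structure(list(segments = segments_from_address_vector(addr),
                        query_len = query_len),
                   class = "domain_assignment")
  if (merge) out <- merge_short_regions(out, params)
  out
}

#' @keywords internal
segments_from_address_vector <- function(addr) {
  n <- length(addr)
  addr[is.na(addr)] <- UNASSIGNED
  brk <- c(0L, which(addr[-1] != addr[-n]), n)
  data.frame(start = brk[-length(brk)] + 1L, end = brk[-1],
             address = addr[brk[-length(brk)] + 1L],
             stringsAsFactors = FALSE)
}

#' Merge short unassigned regions into neighboring domains
#'
#' Every unassigned segment of length `<= min_recurse_len` with at least
#' one assigned neighbor is absorbed: interior segments join the neighbor
#' with the longer adjacent assigned segment (tie: the preceding one);
#' terminal segments join their only neighbor. Unassigned segments
#' without an assigned neighbor are left alone. The result is still a
#' partition of `1..query_len`.
#'
#' @param assignment a `domain_assignment`.
#' @param params an [assign_params()].
#' @return the merged `domain_assignment`.
#' @export
merge_short_regions <- function(assignment, params = assign_params()) {
  seg <- assignment$segments
  repeat {
    # coalesce adjacent segments with identical address
    if (nrow(seg) > 1L) {
      same <- c(FALSE, seg$address[-1] == seg$address[-nrow(seg)])
      if (any(same)) {
        starts <- which(!same)
        ends <- c(starts[-1] - 1L, nrow(seg))
        seg <- data.frame(start = seg$start[starts], end = seg$end[ends],
                          address = seg$address[starts],
                          stringsAsFactors = FALSE)
      }
    }
    len <- seg$end - seg$start + 1L
    k <- which(seg$address == UNASSIGNED & len <= params$min_recurse_len)
    k <- Filter(function(i) {
      (i > 1L && seg$address[i - 1L] != UNASSIGNED) ||
        (i < nrow(seg) && seg$address[i + 1L] != UNASSIGNED)
    }, k)
    if (!length(k)) break
    i <- k[[1]]
    prev_ok <- i > 1L && seg$address[i - 1L] != UNASSIGNED
    next_ok <- i < nrow(seg) && seg$address[i + 1L] != UNASSIGNED
    to_prev <- if (prev_ok && next_ok) {
      len[i - 1L] >= len[i + 1L]  # tie goes to the preceding neighbor
    } else {
      prev_ok
    }
    if (to_prev) {
      seg$end[i - 1L] <- seg$end[i]
    } else {
      seg$start[i + 1L] <- seg$start[i]
    }
    seg <- seg[-i, , drop = FALSE]
    rownames(seg) <- NULL
  }
  assignment$segments <- seg
  assignment
}

#' Check a predicted domain against a reference region
#'
#' Evaluation utility for users with their own reference classification:
#' a prediction is correct for a reference domain region when the
#' predicted region covers at least `min_overlap` of it.
#'
#' @param predicted,reference data.frames with `start`, `end` (closed
#'   intervals) and `address`.
#' @param min_overlap required covered fraction of the reference region
#'   (default 0.8).
#' @return logical vector, one entry per reference row.
#' @export
domain_overlap_correct <- function(predicted, reference, min_overlap = 0.8) {
  vapply(seq_len(nrow(reference)), function(i) {
    rs <- reference$start[i]; re <- reference$end[i]
    p <- predicted[predicted$address == reference$address[i], , drop = FALSE]
    if (!nrow(p)) return(FALSE)
    cov <- sum(pmax(0L, pmin(p$end, re) - pmax(p$start, rs) + 1L))
    cov / (re - rs + 1L) >= min_overlap
  }, logical(1))
}
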