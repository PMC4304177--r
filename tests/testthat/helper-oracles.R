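# Independent oracles, implemented separately from the package code paths
# they check.

# Exhaustive monotone-placement alignment oracle: enumerate every way of
# threading the coordinate sequence into the reference (no gaps in the
# reference), score with match +1 / mismatch 0 / gap-in-coord -0.5, and
# return the first (lexicographically smallest) maximum-score placement.
oracle_align <- function(ref, coord) {
  r <- strsplit(ref, "")[[1]]
  cs <- strsplit(coord, "")[[1]]
  n <- length(r)
  m <- length(cs)
  stopifnot(m <= n)
  placements <- utils::combn(n, m)
  matches <- apply(placements, 2, function(p) sum(cs == r[p]))
  score <- matches - 0.5 * (n - m)
  best <- which(score == max(score))[1]  # combn enumerates lexicographically
  p <- as.integer(placements[, best])
  miss <- setdiff(seq_len(n), p)
  list(map = p, n_matches = max(matches),
       mismatches = p[cs != r[p]], missing = sort(miss))
}

# positions -> closed intervals, local re-implementation
oracle_intervals <- function(pos) {
  if (!length(pos)) return(data.frame(start = integer(0), end = integer(0)))
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1]])
}

# Exhaustive simulator of the 4-step classification protocol, written as an
# iterative worklist over a per-residue address vector (the package uses a
# recursive segment builder). Hit tables are in global query coordinates.
oracle_assign <- function(query_len, seq_hits, struct_hits = NULL,
                          e_max = 0.01, z_min = 4.5, min_len = 30L) {
  addr <- rep(NA_character_, query_len)
  work <- list(c(1L, query_len))
  overlap_clip <- function(h, s, e) {
    if (is.null(h) || !nrow(h)) return(h[integer(0), , drop = FALSE])
    h <- h[h$start <= e & h$end >= s, , drop = FALSE]
    h$start <- pmax(h$start, s)
    h$end <- pmin(h$end, e)
    h
  }
  while (length(work)) {
    iv <- work[[length(work)]]
    work <- work[-length(work)]
    s <- iv[1]; e <- iv[2]
    cand <- overlap_clip(seq_hits, s, e)
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[cand$e_value < e_max & cand$z_score > z_min, ,
                   drop = FALSE]
    }
    if (is.null(cand) || !nrow(cand)) {
      cand <- overlap_clip(struct_hits, s, e)
      if (!is.null(cand) && nrow(cand)) {
        cand <- cand[cand$z_score > z_min, , drop = FALSE]
      }
    }
    if (is.null(cand) || !nrow(cand)) {
      addr[s:e] <- "UNASSIGNED"
      next
    }
    best <- cand[order(-cand$z_score, -cand$target_len, cand$target_id)[1], ]
    addr[best$start:best$end] <- best$address
    gaps <- oracle_intervals((s:e)[is.na(addr[s:e])])
    for (k in seq_len(nrow(gaps))) {
      if (gaps$end[k] - gaps$start[k] + 1L > min_len) {
        work[[length(work) + 1L]] <- c(gaps$start[k], gaps$end[k])
      } else {
        addr[gaps$start[k]:gaps$end[k]] <- "UNASSIGNED"
      }
    }
  }
  # merge short unassigned runs, operating directly on the vector
  repeat {
    runs <- rle(addr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values == "UNASSIGNED" & runs$lengths <= min_len)
    k <- Filter(function(i) {
      (i > 1L && runs$values[i - 1L] != "UNASSIGNED") ||
        (i < length(runs$values) && runs$values[i + 1L] != "UNASSIGNED")
    }, k)
    if (!length(k)) break
    i <- k[[1]]
    prev_ok <- i > 1L && runs$values[i - 1L] != "UNASSIGNED"
    next_ok <- i < length(runs$values) && runs$values[i + 1L] != "UNASSIGNED"
    use_prev <- if (prev_ok && next_ok) {
      runs$lengths[i - 1L] >= runs$lengths[i + 1L]
    } else {
      prev_ok
    }
    src <- if (use_prev) i - 1L else i + 1L
    addr[starts[i]:ends[i]] <- runs$values[src]
  }
  addr
}

# per-residue address vector of a package domain_assignment
assignment_to_vector <- function(da) {
  addr <- rep(NA_character_, da$query_len)
  for (k in seq_len(nrow(da$segments))) {
    addr[da$segments$start[k]:da$segments$end[k]] <- da$segments$address[k]
  }
  addr
}

# Windowed representative rule, re-evaluated on a flat data.frame
oracle_representative <- function(members) {
  df <- data.frame(
    id = vapply(members, function(k) k$id, character(1)),
    len = vapply(members, function(k) k$length, integer(1)),
    effres = vapply(members, function(k) {
      if (!k$is_xray || is.na(k$resolution)) Inf else k$resolution
    }, numeric(1)),
    date = vapply(members, function(k) {
      d <- as.numeric(k$deposit_date)
      if (is.na(d)) -Inf else d
    }, numeric(1)),
    stringsAsFactors = FALSE)
  w <- df[df$len > max(df$len) - 10L, , drop = FALSE]
  w <- w[w$effres == min(w$effres), , drop = FALSE]
  if (all(!is.finite(w$date))) w$date <- 0
  w <- w[w$date == max(w$date), , drop = FALSE]
  sort(w$id)[1]
}

# random scripted hit tables for the protocol oracle
random_hit_table <- function(query_len, n_hits, rng_pool_e, rng_pool_z) {
  if (n_hits == 0L) return(NULL)
  start <- sample.int(query_len, n_hits, replace = TRUE)
  len <- sample.int(query_len, n_hits, replace = TRUE)
  data.frame(
    start = start,
    end = pmin(start + len - 1L, query_len),
    address = sample(c("A.1.1.1", "B.34.9.1", "C.2.1.5", "D.15.1.1"),
                     n_hits, replace = TRUE),
    e_value = sample(rng_pool_e, n_hits, replace = TRUE),
    z_score = sample(rng_pool_z, n_hits, replace = TRUE),
    target_id = sample(sprintf("T%02d", 1:6), n_hits, replace = TRUE),
    target_len = sample(50:300, n_hits, replace = TRUE),
    stringsAsFactors = FALSE)
}

# small helper: fixture -> parsed chain
fixture_chain <- function(fx) parse_pdb(fx$text)[[1]]
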