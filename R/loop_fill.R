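# Missing-region model selection: candidate generation via a pluggable
# backend, an RMSD-of-the-rest filter that keeps the experimental
# structure intact, and lowest-energy selection.

#' Describe a loop-fill task
#'
#' @param chain a cleaned [chain_record()] (residues numbered by
#'   reference position).
#' @param missing_regions data.frame `start`, `end` of reference
#'   positions without coordinates (from [align_ref_coord()]); must be
#'   non-empty.
#' @param n_candidates candidates generated per missing region.
#' @param rmsd_rest_max a candidate whose non-loop RMSD to the
#'   experimental structure is strictly greater than this (Angstrom) is
#'   discarded.
#' @return list of class `loop_task`.
#' @export
loop_task <- function(chain, missing_regions, n_candidates = 500L,
                      rmsd_rest_max = 0.1) {
  stopifnot(n_candidates >= 1L, rmsd_rest_max > 0)
  if (!nrow(missing_regions)) stop("missing_regions must be non-empty")
  structure(list(chain = chain, missing_regions = missing_regions,
                 n_candidates = as.integer(n_candidates),
                 rmsd_rest_max = rmsd_rest_max),
            class = "loop_task")
}

#' @keywords internal
in_regions <- function(pos, regions) {
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(regions))) {
    out <- out | (pos >= regions$start[k] & pos <= regions$end[k])
  }
  out
}

#' RMSD over the structure outside the missing regions
#'
#' Root-mean-square deviation between a candidate model and the original
#' structure over all heavy atoms of residues NOT inside a missing
#' region. Computed in the shared coordinate frame without superposition:
#' the generator is constrained to keep non-loop atoms near their
#' experimental positions, and superposing would mask exactly the drift
#' this quantity exists to catch.
#'
#' @param candidate data.frame of model atoms with columns `res_num`,
#'   `name`, `x`, `y`, `z` covering every reference position.
#' @param original the cleaned [chain_record()].
#' @param missing_regions data.frame `start`, `end`.
#' @return RMSD in Angstrom (0 when coordinates are identical).
#' @export
rmsd_rest <- function(candidate, original, missing_regions) {
  res <- original$residues
  keep_res <- res$res_idx[!in_regions(res$res_num, missing_regions)]
  dev2 <- numeric(0)
  for (ri in keep_res) {
    orig_at <- original$atoms[original$atoms$res_idx == ri, , drop = FALSE]
    rn <- res$res_num[res$res_idx == ri]
    cand_at <- candidate[candidate$res_num == rn, , drop = FALSE]
    idx <- match(orig_at$name, cand_at$name)
    if (anyNA(idx) || nrow(cand_at) != nrow(orig_at)) {
      stop(sprintf("atom-set mismatch on non-loop residue %d", rn))
    }
    dev2 <- c(dev2, (orig_at$x - cand_at$x[idx])^2 +
                (orig_at$y - cand_at$y[idx])^2 +
                (orig_at$z - cand_at$z[idx])^2)
  }
  sqrt(mean(dev2))
}

#' Filter candidates by the RMSD-of-the-rest threshold
#'
#' Keeps exactly the candidates with `rmsd_rest <= rmsd_rest_max`; a
#' candidate strictly above the threshold is removed so the experimental
#' structure stays intact. Order is preserved and the operation is
#' idempotent.
#'
#' @param cands list of candidates, each carrying `rmsd_rest`.
#' @param task a [loop_task()].
#' @return the surviving candidates (possibly an empty list).
#' @export
filter_candidates <- function(cands, task) {
  Filter(function(cd) cd$rmsd_rest <= task$rmsd_rest_max, cands)
}

#' Select the lowest-energy candidate
#'
#' @param cands non-empty list of candidates with `energy` populated
#'   (lower is better). Ties go to the earliest-generated candidate.
#' @return the selected candidate.
#' @export
select_model <- function(cands) {
  if (!length(cands)) stop("no-model error: no surviving candidate")
  en <- vapply(cands, function(cd) cd$energy, numeric(1))
  cands[[which.min(en)]]
}

#' Built-in stub candidate generator
#'
#' Places backbone atoms (N, CA, C, O) for each missing residue by linear
#' interpolation between the anchoring residues' CA positions (or linear
#' extension at chain termini), with seeded Gaussian jitter distinguishing
#' candidates. All non-loop atoms are copied verbatim. The stub exists so
#' the selection protocol is testable end to end; it makes no claim of
#' physical realism.
#'
#' @param chain cleaned [chain_record()].
#' @param region one-row data.frame `start`, `end` (reference positions).
#' @param n number of candidates.
#' @param jitter_sd standard deviation of the positional jitter (A).
#' @return list of `n` candidate atom data.frames (`res_num`, `res_name`,
#'   `name`, `x`, `y`, `z`).
#' @export
stub_generator <- function(chain, region, n, jitter_sd = 0.05) {
  res <- chain$residues
  atoms <- chain$atoms
  base <- data.frame(res_num = res$res_num[match(atoms$res_idx, res$res_idx)],
                     res_name = res$res_name[match(atoms$res_idx,
                                                   res$res_idx)],
                     name = atoms$name, x = atoms$x, y = atoms$y,
                     z = atoms$z, stringsAsFactors = FALSE)
  ca <- base[base$name == "CA", , drop = FALSE]
  s <- region$start; e <- region$end
  L <- e - s + 1L
  prev <- ca[ca$res_num < s, , drop = FALSE]
  nxt <- ca[ca$res_num > e, , drop = FALSE]
  anchor_prev <- if (nrow(prev)) unlist(prev[nrow(prev), c("x", "y", "z")])
                 else NULL
  anchor_next <- if (nrow(nxt)) unlist(nxt[1L, c("x", "y", "z")]) else NULL
  step <- c(3.8, 0, 0)
  if (is.null(anchor_prev) && is.null(anchor_next)) {
    stop("no anchor residues available for region")
  }
  path <- matrix(NA_real_, L, 3)
  for (k in seq_len(L)) {
    t <- k / (L + 1)
    path[k, ] <- if (!is.null(anchor_prev) && !is.null(anchor_next)) {
      anchor_prev + t * (anchor_next - anchor_prev)
    } else if (is.null(anchor_prev)) {
      anchor_next - (L - k + 1L) * step
    } else {
      anchor_prev + k * step
    }
  }
  ref3 <- aa1to3(seq_to_letters(chain$ref_seq))
  lapply(seq_len(n), function(i) {
    new_rows <- do.call(rbind, lapply(seq_len(L), function(k) {
      ctr <- path[k, ] + round(stats::rnorm(3, sd = jitter_sd), 3)
      data.frame(
        res_num = s + k - 1L, res_name = ref3[s + k - 1L],
        name = c("N", "CA", "C", "O"),
        x = round(ctr[1] + c(-0.5, 0, 0.5, 0.6), 3),
        y = round(ctr[2] + c(0.3, 0, 0.3, 1.4), 3),
        z = round(ctr[3], 3), stringsAsFactors = FALSE)
    }))
    out <- rbind(base, new_rows)
    out[order(out$res_num), , drop = FALSE]
  })
}

#' Built-in stub energy backend
#'
#' Deterministic pseudo-energy: the squared deviation of consecutive CA
#' distances from the ideal 3.8 A virtual bond, summed over pairs that
#' involve a modelled residue. Lower is better. Any scorer returning a
#' single real number per candidate (such as an external statistical
#' potential) plugs into the same contract.
#'
#' @param candidate candidate atom data.frame.
#' @param regions data.frame `start`, `end` of modelled regions.
#' @return a single numeric energy.
#' @export
stub_scorer <- function(candidate, regions) {
  ca <- candidate[candidate$name == "CA", , drop = FALSE]
  ca <- ca[order(ca$res_num), , drop = FALSE]
  if (nrow(ca) < 2L) return(0)
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  involved <- in_regions(ca$res_num[-1], regions) |
    in_regions(ca$res_num[-nrow(ca)], regions)
  sum((d[involved] - 3.8)^2)
}

#' Model the missing regions of a chain
#'
#' For each missing region (independently, with its own candidate
#' budget): generate `n_candidates`, compute [rmsd_rest()] for each,
#' discard candidates above `rmsd_rest_max`, score the survivors and keep
#' the lowest-energy model. Modelled regions of length >= 7 residues are
#' flagged low-confidence, as are terminal regions. The returned chain
#' has coordinates for every reference position, with the experimental
#' (non-loop) coordinates unchanged.
#'
#' @param task a [loop_task()].
#' @param generator candidate backend
#'   `(chain, region, n) -> list of candidates`.
#' @param scorer energy backend `(candidate, regions) -> numeric`.
#' @param seed integer seed making generation deterministic.
#' @return list of class `fill_result`: `chain` (completed
#'   [chain_record()]), `report` (data.frame with one row per region:
#'   `start`, `end`, `length`, `n_generated`, `n_after_filter`,
#'   `selected_energy`, `selected_rmsd_rest`, `low_confidence`).
#' @export
fill_chain <- function(task, generator = stub_generator,
                       scorer = stub_scorer, seed = 1L) {
  set.seed(seed)
  chain <- task$chain
  regions <- task$missing_regions
  n_ref <- nchar(chain$ref_seq)
  report <- NULL
  filled <- list()
  for (k in seq_len(nrow(regions))) {
    region <- regions[k, , drop = FALSE]
    cands <- generator(chain, region, task$n_candidates)
    cands <- lapply(cands, function(cd) {
      list(coords = cd,
           rmsd_rest = rmsd_rest(cd, chain, regions),
           energy = NA_real_)
    })
    kept <- filter_candidates(cands, task)
    if (!length(kept)) {
      stop(sprintf(
        "no-model error for region %d-%d: %d generated, 0 after filter",
        region$start, region$end, length(cands)))
    }
    kept <- lapply(kept, function(cd) {
      cd$energy <- scorer(cd$coords, regions)
      cd
    })
    best <- select_model(kept)
    filled[[k]] <- best$coords[in_regions(best$coords$res_num, region), ,
                               drop = FALSE]
    L <- region$end - region$start + 1L
    terminal <- region$start == 1L || region$end == n_ref
    report <- rbind(report, data.frame(
      start = region$start, end = region$end, length = L,
      n_generated = length(cands), n_after_filter = length(kept),
      selected_energy = best$energy, selected_rmsd_rest = best$rmsd_rest,
      low_confidence = L >= 7L || terminal, stringsAsFactors = FALSE))
  }
  new_at <- do.call(rbind, filled)
  # splice modelled residues into the chain record
  res <- chain$residues
  atoms <- chain$atoms
  atoms$res_num <- res$res_num[match(atoms$res_idx, res$res_idx)]
  new_res <- unique(new_at[, c("res_num", "res_name")])
  res2 <- rbind(
    data.frame(res_name = res$res_name, res_num = res$res_num,
               ins_code = " ", is_modified = res$is_modified, het = res$het,
               stringsAsFactors = FALSE),
    data.frame(res_name = new_res$res_name, res_num = new_res$res_num,
               ins_code = " ", is_modified = FALSE, het = FALSE,
               stringsAsFactors = FALSE))
  res2 <- res2[order(res2$res_num), , drop = FALSE]
  res2$res_idx <- seq_len(nrow(res2))
  at2 <- rbind(
    data.frame(res_num = atoms$res_num, name = atoms$name,
               alt_loc = atoms$alt_loc, x = atoms$x, y = atoms$y,
               z = atoms$z, occupancy = atoms$occupancy,
               element = atoms$element, stringsAsFactors = FALSE),
    data.frame(res_num = new_at$res_num, name = new_at$name,
               alt_loc = " ", x = new_at$x, y = new_at$y, z = new_at$z,
               occupancy = 1, element = substr(new_at$name, 1, 1),
               stringsAsFactors = FALSE))
  at2 <- at2[order(at2$res_num), , drop = FALSE]
  at2$res_idx <- res2$res_idx[match(at2$res_num, res2$res_num)]
  at2$serial <- seq_len(nrow(at2))
  chain$residues <- res2[, c("res_idx", "res_name", "res_num", "ins_code",
                             "is_modified", "het")]
  rownames(chain$residues) <- NULL
  chain$atoms <- at2[, c("res_idx", "serial", "name", "alt_loc", "x", "y",
                         "z", "occupancy", "element")]
  rownames(chain$atoms) <- NULL
  structure(list(chain = chain, report = report), class = "fill_result")
}
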