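# Synthetic fixtures: legacy PDB files with planted defects and known
# ground truth, sequence families with planted identity structure, and
# scripted search backends. Every pipeline stage can be exercised against
# these without any external download.

.MODRES_LIBRARY <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                     CSO = "CYS", HYP = "PRO", M3L = "LYS")

#' Describe the defects planted in a chain fixture
#'
#' Each field mirrors one cleaning rule: missing coordinate regions,
#' modified residues restorable via MODRES, alternate-conformation atoms,
#' atoms beyond the standard composition, CA-only structures and unknown
#' residues.
#'
#' @param missing_regions data.frame `start`, `end` (reference
#'   positions) or NULL.
#' @param modres data.frame `position`, `mod_code`, `std_code` or NULL.
#' @param altloc_atoms data.frame `position`, `name`, `n_variants` or
#'   NULL.
#' @param extra_atoms data.frame `position`, `name` or NULL.
#' @param ca_only emit only CA atoms.
#' @param x_positions integer vector of unknown (UNK/X) residues.
#' @param oxt_last add a terminal OXT to the last coordinate residue.
#' @return list of class `defect_spec`.
#' @export
defect_spec <- function(missing_regions = NULL, modres = NULL,
                        altloc_atoms = NULL, extra_atoms = NULL,
                        ca_only = FALSE, x_positions = integer(0),
                        oxt_last = FALSE) {
  if (is.null(missing_regions)) {
    missing_regions <- data.frame(start = integer(0), end = integer(0))
  }
  structure(list(missing_regions = missing_regions, modres = modres,
                 altloc_atoms = altloc_atoms, extra_atoms = extra_atoms,
                 ca_only = isTRUE(ca_only),
                 x_positions = as.integer(x_positions),
                 oxt_last = isTRUE(oxt_last)),
            class = "defect_spec")
}

.validate_defects <- function(seq, defects) {
  n <- nchar(seq)
  mr <- defects$missing_regions
  if (nrow(mr)) {
    if (any(mr$start < 1L | mr$end > n | mr$start > mr$end)) {
      stop("inconsistent defect spec: missing region outside sequence")
    }
    mr <- mr[order(mr$start), , drop = FALSE]
    if (nrow(mr) > 1L && any(mr$start[-1] <= mr$end[-nrow(mr)])) {
      stop("inconsistent defect spec: overlapping missing regions")
    }
    if (all(in_regions(seq_len(n), mr))) {
      stop("inconsistent defect spec: no coordinate residues left")
    }
  }
  point_pos <- c(if (!is.null(defects$modres)) defects$modres$position,
                 defects$x_positions,
                 if (!is.null(defects$altloc_atoms))
                   defects$altloc_atoms$position,
                 if (!is.null(defects$extra_atoms))
                   defects$extra_atoms$position)
  if (length(point_pos) && any(point_pos < 1L | point_pos > n)) {
    stop("inconsistent defect spec: defect position outside sequence")
  }
  # point defects must not sit inside (or within 1 residue of) a missing
  # region, which keeps the planted alignment unambiguous
  near <- c(if (!is.null(defects$modres)) defects$modres$position,
            defects$x_positions)
  if (length(near) && nrow(mr)) {
    grown <- data.frame(start = pmax(1L, mr$start - 1L),
                        end = pmin(n, mr$end + 1L))
    if (any(in_regions(near, grown))) {
      stop("inconsistent defect spec: modres/X position adjacent to a missing region")
    }
  }
  others <- c(if (!is.null(defects$altloc_atoms))
                defects$altloc_atoms$position,
              if (!is.null(defects$extra_atoms)) defects$extra_atoms$position)
  if (length(others) && nrow(mr) && any(in_regions(others, mr))) {
    stop("inconsistent defect spec: atom defect inside a missing region")
  }
  mp <- if (!is.null(defects$modres)) defects$modres$position else integer(0)
  if (anyDuplicated(c(mp, defects$x_positions))) {
    stop("inconsistent defect spec: duplicated residue-level defect positions")
  }
  invisible(mr)
}

# deterministic atom offsets around the CA of a residue
.atom_offsets <- function(names) {
  base <- list(N = c(-0.6, 0.9, 0.1), CA = c(0, 0, 0), C = c(0.6, 0.9, -0.1),
               O = c(0.7, 2.1, 0.2), OXT = c(1.4, 2.4, 0.4))
  out <- matrix(NA_real_, length(names), 3)
  side <- 0L
  for (i in seq_along(names)) {
    if (!is.null(base[[names[i]]])) {
      out[i, ] <- base[[names[i]]]
    } else {
      side <- side + 1L
      out[i, ] <- c(0.15 * side, -1.1 - 0.35 * side, 0.3 + 0.05 * side)
    }
  }
  out
}

#' Generate a legacy PDB fixture with planted defects
#'
#' Emits a fixed-column legacy PDB file embodying exactly the requested
#' defects over an idealized extended backbone, together with the ground
#' truth the cleaning pipeline must recover: the reference and
#' coordinate sequences, missing regions, restored/mismatch positions,
#' pruned-atom counts and the filter verdict.
#'
#' Ground truth for the alignment assumes the planted alignment is the
#' unique optimum, which holds for sequences without short-period repeats
#' around the planted regions; [make_clean_suite()] generates sequences
#' from a maximally diverse rotating alphabet so this is guaranteed.
#'
#' @param seq 1-letter sequence using the 20 standard letters.
#' @param defects a [defect_spec()].
#' @param seed integer seed for the coordinate jitter.
#' @param meta a [chain_meta()] for the emitted header records.
#' @return list of class `chain_fixture` with `text` (PDB lines) and
#'   `truth` (list of expected post-cleaning facts).
#' @export
make_chain_fixture <- function(seq, defects = defect_spec(), seed = 1L,
                               meta = chain_meta(pdb_id = "SYN1",
                                                 chain_id = "A",
                                                 method = "XRAY",
                                                 resolution = 2.0,
                                                 deposit_date = "2006-12-05",
                                                 source = "SYNTHETIC")) {
  stopifnot(nchar(seq) >= 1L)
  letters1 <- seq_to_letters(seq)
  if (!all(letters1 %in% unname(.AA_321))) {
    stop("seq must use the 20 standard letters")
  }
  mr <- .validate_defects(seq, defects)
  set.seed(seed)
  n <- nchar(seq)

  modres <- defects$modres
  mod_at <- if (is.null(modres)) integer(0) else modres$position
  xpos <- defects$x_positions

  # per-position 3-letter codes as SEQRES will list them
  seqres3 <- aa1to3(letters1)
  if (length(xpos)) seqres3[xpos] <- "UNK"
  if (length(mod_at)) seqres3[mod_at] <- modres$mod_code

  # expected reference sequence after 1-letter translation
  ref_expect <- paste(aa3to1(seqres3), collapse = "")

  coord_pos <- setdiff(seq_len(n), unlist(lapply(seq_len(nrow(mr)),
                       function(k) mr$start[k]:mr$end[k])))
  # coordinate residue names as emitted (modified codes kept in the file)
  emit3 <- seqres3[coord_pos]
  # names after restoration
  restored3 <- emit3
  if (length(mod_at)) {
    hit <- coord_pos %in% mod_at
    restored3[hit] <- modres$std_code[match(coord_pos[hit], modres$position)]
  }
  coord_expect <- paste(aa3to1(restored3), collapse = "")

  lines <- character(0)
  lines <- c(lines, sprintf("%-10s%-40s%9s   %4s", "HEADER", "PROTEIN",
                            format_pdb_date(meta$deposit_date),
                            meta$pdb_id))
  lines <- c(lines, sprintf("EXPDTA    %s",
                            switch(meta$method, XRAY = "X-RAY DIFFRACTION",
                                   NMR = "SOLUTION NMR", OTHER = "OTHER")))
  lines <- c(lines, if (!is.na(meta$resolution)) {
    sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", meta$resolution)
  } else "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  if (nzchar(meta$source)) lines <- c(lines, sprintf("SOURCE    %s",
                                                     meta$source))
  ser <- 1L
  for (i in seq(1L, n, by = 13L)) {
    blk <- seqres3[i:min(i + 12L, n)]
    lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", ser, meta$chain_id,
                              n, paste(sprintf("%-3s", blk), collapse = " ")))
    ser <- ser + 1L
  }
  if (length(mod_at)) {
    for (k in seq_len(nrow(modres))) {
      lines <- c(lines, sprintf("MODRES %4s %3s %1s %4d%1s %3s  %s",
                                meta$pdb_id, modres$mod_code[k],
                                meta$chain_id, modres$position[k], " ",
                                modres$std_code[k], "MODIFIED RESIDUE"))
    }
  }

  n_pruned_expect <- 0L
  n_alt_removed <- 0L
  serial <- 0L
  last_coord <- coord_pos[length(coord_pos)]
  for (j in seq_along(coord_pos)) {
    p <- coord_pos[j]
    rname <- emit3[j]
    is_mod <- p %in% mod_at
    comp_name <- if (is_mod) {
      modres$std_code[match(p, modres$position)]
    } else rname
    atom_names <- if (defects$ca_only) {
      "CA"
    } else {
      comp <- .AA_HEAVY_ATOMS[[comp_name]]
      if (is.null(comp)) comp <- .AA_HEAVY_ATOMS$UNK
      comp
    }
    # selenomethionine-style realism: the modified residue carries one
    # atom beyond the standard composition of its parent, later pruned
    if (is_mod && !defects$ca_only && rname == "MSE") {
      atom_names[atom_names == "SD"] <- "SE"
      n_pruned_expect <- n_pruned_expect + 1L
    }
    if (!is.null(defects$extra_atoms) && !defects$ca_only) {
      ex <- defects$extra_atoms[defects$extra_atoms$position == p, ,
                                drop = FALSE]
      if (nrow(ex)) {
        if (any(ex$name %in% .AA_HEAVY_ATOMS[[comp_name]])) {
          stop("inconsistent defect spec: extra atom is part of the standard composition")
        }
        atom_names <- c(atom_names, ex$name)
        n_pruned_expect <- n_pruned_expect + nrow(ex)
      }
    }
    if (defects$oxt_last && p == last_coord && !defects$ca_only) {
      atom_names <- c(atom_names, "OXT")
    }
    off <- .atom_offsets(atom_names)
    ca_xyz <- c(3.8 * p, round(stats::rnorm(1, 0, 0.2), 3),
                round(stats::rnorm(1, 0, 0.2), 3))
    rectype <- if (is_mod) "HETATM" else "ATOM  "
    for (a in seq_along(atom_names)) {
      nvar <- 1L
      if (!is.null(defects$altloc_atoms) && !defects$ca_only) {
        av <- defects$altloc_atoms
        hit <- av$position == p & av$name == atom_names[a]
        if (any(hit)) nvar <- av$n_variants[which(hit)[1]]
      }
      for (v in seq_len(nvar)) {
        serial <- serial + 1L
        alt <- if (nvar > 1L) LETTERS[v] else " "
        xyz <- round(ca_xyz + off[a, ] + c(0, 0.4, 0) * (v - 1L), 3)
        lines <- c(lines, sprintf(
          "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, fmt_atom_name(atom_names[a]), alt, rname, meta$chain_id,
          p, " ", xyz[1], xyz[2], xyz[3],
          round(1 / nvar, 2), 0, substr(atom_names[a], 1, 1)))
        # HETATM record type for modified residues
        if (rectype == "HETATM") {
          substr(lines[length(lines)], 1, 6) <- "HETATM"
        }
      }
      if (nvar > 1L) n_alt_removed <- n_alt_removed + nvar - 1L
    }
  }
  lines <- c(lines, "END")

  reasons <- character(0)
  if (defects$ca_only) reasons <- c(reasons, "CA_ONLY")
  if (n < 30L) reasons <- c(reasons, "TOO_SHORT")
  if (mean(seq_to_letters(ref_expect) == "X") > 0.10) {
    reasons <- c(reasons, "TOO_MANY_X")
  }

  truth <- list(
    ref_seq = ref_expect,
    coord_seq = coord_expect,
    missing_regions = mr,
    map = coord_pos,
    mismatch_positions = sort(intersect(coord_pos, mod_at)),
    restored_res = which(coord_pos %in% mod_at),
    n_atoms_pruned = if (defects$ca_only) 0L else n_pruned_expect,
    n_altloc_removed = n_alt_removed,
    kept = length(reasons) == 0L,
    reasons = reasons
  )
  structure(list(text = lines, truth = truth, meta = meta,
                 defects = defects), class = "chain_fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# size-safe sampling (sample() misbehaves on length-1 vectors)
.pick <- function(x, k = 1L) x[sample.int(length(x), k)]

#' Generate a randomized cleaning-suite of fixtures
#'
#' Random sequences over a rotating 20-letter alphabet (so planted
#' alignments are provably unique) with randomized defect specs, plus
#' deterministic boundary cases: the length-29/30 filter boundary, a
#' CA-only chain and a chain with too many unknown residues.
#'
#' @param n_chains number of fixtures.
#' @param seed integer seed.
#' @return list of `chain_fixture` objects.
#' @export
make_clean_suite <- function(n_chains = 200L, seed = 1L) {
  set.seed(seed)
  aa <- unname(.AA_321)
  rot_seq <- function(len) {
    perm <- sample(aa)
    paste(perm[((seq_len(len) - 1L) %% 20L) + 1L], collapse = "")
  }
  rand_date <- function() {
    as.Date("1985-01-01") + sample.int(10000L, 1L)
  }
  out <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    kind <- if (i == 1L) "len29" else if (i == 2L) "len30"
            else if (i == 3L) "ca_only" else if (i == 4L) "many_x"
            else "random"
    len <- switch(kind, len29 = 29L, len30 = 30L, .pick(32:70))
    seq <- rot_seq(len)
    defects <- switch(kind,
      len29 = defect_spec(),
      len30 = defect_spec(),
      ca_only = defect_spec(ca_only = TRUE),
      many_x = defect_spec(x_positions = seq(2L, by = 3L,
                                             length.out = ceiling(len / 6))),
      {
        # random interior/terminal missing regions, pairwise separated
        mr <- NULL
        n_reg <- sample(0:2, 1L)
        if (n_reg > 0L) {
          cand <- list()
          lo <- 1L
          for (r in seq_len(n_reg)) {
            if (lo > len - 6L) break
            st <- .pick(lo:min(lo + 15L, len - 5L))
            en <- min(st + .pick(0:6), len - 4L)
            cand[[length(cand) + 1L]] <- c(st, en)
            lo <- en + 5L
          }
          if (length(cand)) {
            mr <- data.frame(start = vapply(cand, `[`, integer(1), 1L),
                             end = vapply(cand, `[`, integer(1), 2L))
          }
        }
        block <- function(k) {
          # candidate positions at distance >= 2 from planted regions
          pos <- seq_len(len)
          if (!is.null(mr)) {
            grown <- data.frame(start = pmax(1L, mr$start - 2L),
                                end = pmin(len, mr$end + 2L))
            pos <- pos[!in_regions(pos, grown)]
          }
          if (length(pos) < k) integer(0) else sort(.pick(pos, k))
        }
        n_mod <- .pick(0:2)
        n_x <- .pick(0:1)
        picks <- block(n_mod + n_x)
        modres <- NULL
        xpos <- integer(0)
        if (length(picks) == n_mod + n_x) {
          if (n_mod > 0L) {
            codes <- sample(names(.MODRES_LIBRARY), n_mod)
            modres <- data.frame(position = picks[seq_len(n_mod)],
                                 mod_code = codes,
                                 std_code = unname(.MODRES_LIBRARY[codes]),
                                 stringsAsFactors = FALSE)
          }
          if (n_x > 0L) xpos <- picks[n_mod + seq_len(n_x)]
        }
        coord_ok <- setdiff(seq_len(len),
                            if (is.null(mr)) integer(0)
                            else unlist(mapply(function(s, e) s:e,
                                               mr$start, mr$end,
                                               SIMPLIFY = FALSE)))
        extra <- NULL
        if (stats::runif(1) < 0.5 && length(coord_ok)) {
          extra <- data.frame(position = .pick(coord_ok), name = "ZZ1",
                              stringsAsFactors = FALSE)
        }
        altloc <- NULL
        if (stats::runif(1) < 0.5 && length(coord_ok)) {
          altloc <- data.frame(position = .pick(coord_ok), name = "CA",
                               n_variants = .pick(2:3))
        }
        defect_spec(missing_regions = mr, modres = modres,
                    altloc_atoms = altloc, extra_atoms = extra,
                    x_positions = xpos,
                    oxt_last = stats::runif(1) < 0.3)
      })
    method <- sample(c("XRAY", "XRAY", "NMR", "OTHER"), 1L)
    meta <- chain_meta(
      pdb_id = sprintf("S%03d", i %% 1000L),
      chain_id = sample(LETTERS, 1L), method = method,
      resolution = if (method == "XRAY") round(stats::runif(1, 1, 3.5), 2)
                   else NA_real_,
      deposit_date = rand_date(), source = "SYNTHETIC")
    out[[i]] <- make_chain_fixture(seq, defects,
                                   seed = sample.int(1e6L, 1L), meta = meta)
  }
  out
}

#' Describe a planted sequence family
#'
#' @param group_sizes integer vector, one entry per planted group.
#' @param base_length base sequence length (residues).
#' @param within_identity target pairwise identity inside a group.
#' @param between_max upper bound on cross-group similarity (checked on
#'   the realized sequences).
#' @param length_deltas per-member length changes (recycled); keep small
#'   relative to `base_length` so identity targets stay achievable.
#' @param resolutions,methods,dates per-member metadata (recycled).
#' @return list of class `family_spec`.
#' @export
family_spec <- function(group_sizes = c(3L, 3L), base_length = 120L,
                        within_identity = 0.95, between_max = 0.35,
                        length_deltas = 0L, resolutions = 2.0,
                        methods = "XRAY", dates = "2010-06-01") {
  stopifnot(all(group_sizes >= 1L), within_identity > 0,
            within_identity <= 1)
  n <- sum(group_sizes)
  structure(list(group_sizes = as.integer(group_sizes),
                 base_length = as.integer(base_length),
                 within_identity = within_identity,
                 between_max = between_max,
                 length_deltas = rep_len(as.integer(length_deltas), n),
                 resolutions = rep_len(resolutions, n),
                 methods = rep_len(methods, n),
                 dates = rep_len(as.Date(dates), n)),
            class = "family_spec")
}

#' Generate a sequence family with planted identity structure
#'
#' Each group derives its members from a private random base sequence by
#' per-position substitution at rate `(1 - within_identity) / 2`, so that
#' the realized pairwise identity inside a group lands near the target.
#' Realized similarities are verified with the built-in aligner: within
#' a group they must be within 3 percentage points of the target, across
#' groups they must stay below `between_max`; otherwise the targets are
#' declared infeasible.
#'
#' @param spec a [family_spec()].
#' @param seed integer seed.
#' @return list of class `sequence_family`: `seqs` (named), `keys`
#'   (named list of [priority_key()]s), `partition` (named group index),
#'   `similarity` (realized matrix), `fasta` (lines).
#' @export
make_family <- function(spec, seed = 1L) {
  set.seed(seed)
  aa <- unname(.AA_321)
  n <- sum(spec$group_sizes)
  ids <- sprintf("M%02d", seq_len(n))
  group <- rep(seq_along(spec$group_sizes), spec$group_sizes)
  names(group) <- ids
  mut_rate <- (1 - spec$within_identity) / 2
  seqs <- character(n)
  for (g in seq_along(spec$group_sizes)) {
    base <- sample(aa, spec$base_length, replace = TRUE)
    for (i in which(group == g)) {
      s <- base
      nmut <- round(mut_rate * length(s))
      if (nmut > 0L) {
        at <- sample(length(s), nmut)
        s[at] <- vapply(s[at], function(x) sample(setdiff(aa, x), 1L),
                        character(1))
      }
      d <- spec$length_deltas[i]
      if (d < 0L) s <- s[seq_len(length(s) + d)]
      if (d > 0L) s <- c(s, sample(aa, d, replace = TRUE))
      seqs[i] <- paste(s, collapse = "")
    }
  }
  names(seqs) <- ids
  sim <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- pairwise_similarity(seqs[i], seqs[j])$value
      sim[i, j] <- v
      sim[j, i] <- v
    }
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (group[i] == group[j]) {
        if (abs(sim[i, j] - spec$within_identity) > 0.03) {
          stop(sprintf(
            "infeasible identity targets: realized %.3f for pair %s-%s (target %.2f)",
            sim[i, j], ids[i], ids[j], spec$within_identity))
        }
      } else if (sim[i, j] > spec$between_max) {
        stop(sprintf(
          "infeasible identity targets: cross-group pair %s-%s realized %.3f > %.2f",
          ids[i], ids[j], sim[i, j], spec$between_max))
      }
    }
  }
  keys <- lapply(seq_len(n), function(i) {
    priority_key(ids[i], nchar(seqs[i]),
                 is_xray = spec$methods[i] == "XRAY",
                 resolution = spec$resolutions[i],
                 deposit_date = spec$dates[i])
  })
  names(keys) <- ids
  fasta <- unlist(lapply(ids, function(id) c(paste0(">", id), seqs[[id]])))
  structure(list(seqs = seqs, keys = keys, partition = group,
                 similarity = sim, fasta = fasta),
            class = "sequence_family")
}

#' Build a scripted search backend from a hit table
#'
#' Returns a backend function `(start, end)` that yields exactly the
#' given hits for the full query and clipped, re-localized hits for
#' recursed subqueries: a hit overlapping the queried interval is
#' returned with its span intersected with the interval and shifted to
#' interval-local coordinates.
#'
#' @param hits data.frame with columns `start`, `end` (global query
#'   coordinates), `address`, and optionally `e_value`, `z_score`,
#'   `target_id`, `target_len`.
#' @return a backend function for [assign_domains()].
#' @export
make_hit_script <- function(hits) {
  if (is.null(hits) || !nrow(hits)) {
    return(function(s, e) empty_hits())
  }
  if (is.null(hits$e_value)) hits$e_value <- 1e-5
  if (is.null(hits$z_score)) hits$z_score <- 10
  if (is.null(hits$target_id)) {
    hits$target_id <- sprintf("D%02d", seq_len(nrow(hits)))
  }
  if (is.null(hits$target_len)) hits$target_len <- hits$end - hits$start + 1L
  force(hits)
  function(s, e) {
    sel <- hits$start <= e & hits$end >= s
    h <- hits[sel, , drop = FALSE]
    if (!nrow(h)) return(empty_hits())
    data.frame(target_id = h$target_id, target_address = h$address,
               e_value = h$e_value, z_score = h$z_score,
               query_start = pmax(h$start, s) - s + 1L,
               query_end = pmin(h$end, e) - s + 1L,
               target_len = h$target_len, stringsAsFactors = FALSE)
  }
}
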