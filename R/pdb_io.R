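# Legacy fixed-column PDB parsing and writing at chain granularity.
#
# Only the legacy dialect is handled (HEADER, EXPDTA, REMARK 2, SOURCE,
# SEQRES, MODRES, ATOM/HETATM, MODEL/ENDMDL, TER, END). mmCIF is out of
# scope. Multi-model files contribute only their first model.

#' Construct chain metadata
#'
#' @param pdb_id 4-character PDB identifier.
#' @param chain_id 1-character chain identifier.
#' @param method experimental method, one of `"XRAY"`, `"NMR"`, `"OTHER"`.
#' @param resolution resolution in Angstrom, or `NA` (always `NA` for NMR).
#' @param deposit_date a `Date` (or string coercible to one).
#' @param source free-text source organism / description.
#' @return a list of class `chain_meta`.
#' @export
chain_meta <- function(pdb_id = "XXXX", chain_id = "A",
                       method = c("XRAY", "NMR", "OTHER"),
                       resolution = NA_real_,
                       deposit_date = as.Date(NA), source = "") {
  method <- match.arg(method)
  resolution <- as.numeric(resolution)
  if (method != "XRAY") resolution <- NA_real_
  if (!is.na(resolution) && resolution <= 0) {
    stop("resolution must be positive when present")
  }
  structure(list(pdb_id = pdb_id, chain_id = chain_id, method = method,
                 resolution = resolution,
                 deposit_date = as.Date(deposit_date), source = source),
            class = "chain_meta")
}

#' Construct a chain record
#'
#' The unit every other operation in the package works on: one protein
#' chain with its reference (SEQRES) sequence, its coordinate residues and
#' its experiment metadata.
#'
#' @param meta a [chain_meta()] object.
#' @param ref_seq 1-letter reference sequence (20 standard letters plus
#'   `"X"`).
#' @param residues data.frame with columns `res_idx`, `res_name`,
#'   `res_num`, `ins_code`, `is_modified`, `het` (one row per coordinate
#'   residue, in file order).
#' @param atoms data.frame with columns `res_idx`, `serial`, `name`,
#'   `alt_loc`, `x`, `y`, `z`, `occupancy`, `element`.
#' @param modres_map named character vector mapping modified 3-letter codes
#'   to standard 3-letter codes for this file.
#' @param seqres_missing flag: `TRUE` when the file had no SEQRES for the
#'   chain and `ref_seq` was derived from the coordinates.
#' @return a list of class `chain_record`.
#' @export
chain_record <- function(meta, ref_seq, residues, atoms,
                         modres_map = character(0), seqres_missing = FALSE) {
  stopifnot(inherits(meta, "chain_meta"), is.character(ref_seq),
            nchar(ref_seq) >= 1L)
  bad <- setdiff(seq_to_letters(ref_seq), c(names(.AA_123)))
  if (length(bad)) stop("ref_seq contains invalid letters: ",
                        paste(bad, collapse = ""))
  structure(list(meta = meta, ref_seq = ref_seq, residues = residues,
                 atoms = atoms, modres_map = modres_map,
                 seqres_missing = isTRUE(seqres_missing)),
            class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record %s_%s>\n", x$meta$pdb_id, x$meta$chain_id))
  cat(sprintf("  method: %s  resolution: %s  deposited: %s\n",
              x$meta$method,
              ifelse(is.na(x$meta$resolution), "-",
                     format(x$meta$resolution)),
              format(x$meta$deposit_date)))
  cat(sprintf("  ref_seq (%d aa): %s%s\n", nchar(x$ref_seq),
              substr(x$ref_seq, 1, 50),
              if (nchar(x$ref_seq) > 50) "..." else ""))
  cat(sprintf("  %d coordinate residues, %d atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' 1-letter sequence of the coordinate part of a chain
#'
#' @param chain a [chain_record()].
#' @return a 1-letter string, one letter per coordinate residue
#'   (non-standard residue names contribute `"X"`).
#' @export
coord_sequence <- function(chain) {
  paste(aa3to1(chain$residues$res_name), collapse = "")
}

.pdb_months <- c(JAN = 1L, FEB = 2L, MAR = 3L, APR = 4L, MAY = 5L, JUN = 6L,
                 JUL = 7L, AUG = 8L, SEP = 9L, OCT = 10L, NOV = 11L,
                 DEC = 12L)

# dd-MMM-yy with two-digit-year pivot 71 (>= 71 -> 19xx, else 20xx); the
# earliest PDB depositions date from 1972.
parse_pdb_date <- function(s, line_no = NA_integer_) {
  s <- trimws(s)
  if (s == "") return(as.Date(NA))
  m <- regmatches(s, regexec("^([0-9]{2})-([A-Z]{3})-([0-9]{2})$", s))[[1]]
  if (length(m) != 4L || is.na(.pdb_months[m[3]])) {
    stop(sprintf("parse error at line %s: bad deposit date '%s'",
                 line_no, s))
  }
  yy <- as.integer(m[4])
  year <- if (yy >= 71L) 1900L + yy else 2000L + yy
  as.Date(sprintf("%04d-%02d-%02d", year, .pdb_months[m[3]],
                  as.integer(m[2])))
}

format_pdb_date <- function(d) {
  if (is.na(d)) return("")
  toupper(format(d, "%d-%b-%y"))
}

.num_field <- function(s, what, line_no) {
  out <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(out) & trimws(s) != "")
  bad2 <- which(trimws(s) == "")
  bad <- sort(c(bad, bad2))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: bad %s field '%s'",
                 line_no[bad[1]], what, s[bad[1]]))
  }
  out
}

#' Parse a legacy PDB file into chain records
#'
#' One [chain_record()] is produced per distinct chain identifier that has
#' ATOM records. SEQRES is translated to 1-letter codes (unknown 3-letter
#' codes map to `"X"`), MODRES records are collected into `modres_map`, and
#' HETATM residues are retained only when their residue name is covered by
#' a MODRES record (so modified residues listed in SEQRES survive while
#' waters and ligands are dropped). For multi-model (typically NMR) files
#' only the first model is read. Chains present in SEQRES but without any
#' ATOM record are skipped with a message.
#'
#' @param text a file path, a single string containing the whole file, or a
#'   character vector of lines.
#' @return a named list of [chain_record()]s (names `pdbid_chain`).
#' @export
parse_pdb <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  if (!length(lines)) stop("empty PDB input")
  pad <- function(l) formatC(l, width = 80, flag = "-")
  lines <- pad(lines)
  rec <- substr(lines, 1, 6)
  n <- length(lines)
  line_no <- seq_len(n)

  # header-level metadata
  pdb_id <- "XXXX"; dep_date <- as.Date(NA)
  hidx <- which(rec == "HEADER")
  if (length(hidx)) {
    h <- lines[hidx[1]]
    id <- trimws(substr(h, 63, 66))
    if (nzchar(id)) pdb_id <- id
    dep_date <- parse_pdb_date(substr(h, 51, 59), hidx[1])
  }
  method <- "OTHER"
  eidx <- which(rec == "EXPDTA")
  if (length(eidx)) {
    ex <- toupper(paste(trimws(substr(lines[eidx], 11, 79)), collapse = " "))
    if (grepl("X-RAY|XRAY", ex)) method <- "XRAY"
    else if (grepl("NMR", ex)) method <- "NMR"
  }
  resolution <- NA_real_
  ridx <- which(rec == "REMARK" & grepl("RESOLUTION", lines, fixed = TRUE) &
                trimws(substr(lines, 8, 10)) == "2")
  if (length(ridx)) {
    rl <- lines[ridx[1]]
    m <- regmatches(rl, regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                                rl, perl = TRUE))
    if (length(m)) resolution <- as.numeric(m)
  }
  if (method == "NMR") resolution <- NA_real_
  src <- ""
  sidx <- which(rec == "SOURCE")
  if (length(sidx)) {
    src <- trimws(paste(trimws(substr(lines[sidx], 11, 79)), collapse = " "))
  }

  # SEQRES per chain
  seqres <- list()
  qidx <- which(rec == "SEQRES")
  for (i in qidx) {
    l <- lines[i]
    ch <- substr(l, 12, 12)
    codes <- strsplit(trimws(substr(l, 20, 80)), "[[:space:]]+")[[1]]
    codes <- codes[nzchar(codes)]
    seqres[[ch]] <- c(seqres[[ch]], codes)
  }

  # MODRES map (modified code -> standard code), file-level
  modres_map <- character(0)
  midx <- which(rec == "MODRES")
  for (i in midx) {
    l <- lines[i]
    from <- trimws(substr(l, 13, 15))
    to <- trimws(substr(l, 25, 27))
    if (!nzchar(from) || !nzchar(to)) {
      stop(sprintf("parse error at line %d: malformed MODRES record", i))
    }
    modres_map[from] <- to
  }

  # restrict coordinates to the first model when MODEL records are present
  coord_ok <- rep(TRUE, n)
  mstart <- which(rec == "MODEL ")
  if (length(mstart)) {
    mend <- which(rec == "ENDMDL")
    stop1 <- if (length(mend)) mend[mend > mstart[1]][1] else NA_integer_
    if (is.na(stop1)) stop1 <- n + 1L
    coord_ok <- line_no > mstart[1] & line_no < stop1
  }

  is_atom <- rec == "ATOM  " & coord_ok
  is_het <- rec == "HETATM" & coord_ok
  sel <- which(is_atom | is_het)
  if (!length(which(is_atom))) stop("no ATOM records found")

  al <- lines[sel]
  aln_no <- line_no[sel]
  at <- data.frame(
    line = aln_no,
    het = is_het[sel],
    serial = as.integer(.num_field(substr(al, 7, 11), "serial", aln_no)),
    name = trimws(substr(al, 13, 16)),
    alt_loc = substr(al, 17, 17),
    res_name = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    res_num = as.integer(.num_field(substr(al, 23, 26), "residue number",
                                    aln_no)),
    ins_code = substr(al, 27, 27),
    x = .num_field(substr(al, 31, 38), "x", aln_no),
    y = .num_field(substr(al, 39, 46), "y", aln_no),
    z = .num_field(substr(al, 47, 54), "z", aln_no),
    occupancy = .num_field(substr(al, 55, 60), "occupancy", aln_no),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(at$name))) {
    stop(sprintf("parse error at line %d: empty atom name",
                 at$line[which(!nzchar(at$name))[1]]))
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in ATOM records")
  }
  # HETATM kept only when MODRES identifies the residue as a modified
  # standard residue; everything else (waters, ligands) is dropped
  at <- at[!at$het | at$res_name %in% names(modres_map), , drop = FALSE]

  chains_atoms <- unique(at$chain)
  skipped <- setdiff(names(seqres), chains_atoms)
  if (length(skipped)) {
    message("skipping chain(s) with SEQRES but no ATOM records: ",
            paste(skipped, collapse = ", "))
  }

  out <- list()
  for (ch in chains_atoms) {
    ca <- at[at$chain == ch, , drop = FALSE]
    key <- paste0(ca$res_num, "|", ca$ins_code)
    ridx <- c(1L, cumsum(key[-1] != key[-length(key)]) + 1L)
    residues <- data.frame(
      res_idx = seq_len(max(ridx)),
      res_name = ca$res_name[!duplicated(ridx)],
      res_num = ca$res_num[!duplicated(ridx)],
      ins_code = ca$ins_code[!duplicated(ridx)],
      is_modified = FALSE,
      het = ca$het[!duplicated(ridx)],
      stringsAsFactors = FALSE
    )
    atoms <- data.frame(res_idx = ridx, serial = ca$serial, name = ca$name,
                        alt_loc = ca$alt_loc, x = ca$x, y = ca$y, z = ca$z,
                        occupancy = ca$occupancy, element = ca$element,
                        stringsAsFactors = FALSE)
    dup <- duplicated(paste0(ridx, "|", ca$name, "|", ca$alt_loc))
    if (any(dup)) {
      stop(sprintf(
        "parse error at line %d: duplicate atom '%s' (altLoc '%s') in residue",
        ca$line[which(dup)[1]], ca$name[which(dup)[1]],
        ca$alt_loc[which(dup)[1]]))
    }
    sr <- seqres[[ch]]
    seqres_missing <- is.null(sr)
    ref_seq <- if (seqres_missing) {
      paste(aa3to1(residues$res_name), collapse = "")
    } else {
      paste(aa3to1(sr), collapse = "")
    }
    meta <- chain_meta(pdb_id = pdb_id, chain_id = ch, method = method,
                      resolution = resolution, deposit_date = dep_date,
                      source = src)
    out[[paste0(pdb_id, "_", ch)]] <-
      chain_record(meta, ref_seq, residues, atoms, modres_map,
                   seqres_missing)
  }
  out
}

fmt_atom_name <- function(name) {
  # standard convention: names of up to 3 characters start in column 14
  ifelse(nchar(name) >= 4L, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write a cleaned chain record as legacy PDB text
#'
#' Serializes SEQRES (from `ref_seq`), MODRES (from `modres_map`) and ATOM
#' records in fixed-column legacy layout. The chain is expected to have
#' been cleaned: a single conformation per atom and standard residue
#' names. Re-parsing the output reproduces the chain's sequences,
#' coordinates and metadata.
#'
#' @param chain a cleaned [chain_record()].
#' @return character vector of PDB lines.
#' @export
write_clean_pdb <- function(chain) {
  m <- chain$meta
  res <- chain$residues
  atoms <- chain$atoms
  for (i in res$res_idx) {
    nm <- atoms$name[atoms$res_idx == i]
    if (anyDuplicated(nm)) {
      stop(sprintf("serialization error: duplicate atom name '%s' in residue %d",
                   nm[duplicated(nm)][1], i))
    }
  }
  out <- character(0)
  out <- c(out, sprintf("%-10s%-40s%9s   %4s", "HEADER", "PROTEIN",
                        format_pdb_date(m$deposit_date), m$pdb_id))
  expdta <- switch(m$method, XRAY = "X-RAY DIFFRACTION",
                   NMR = "SOLUTION NMR", OTHER = "OTHER")
  out <- c(out, sprintf("EXPDTA    %s", expdta))
  if (!is.na(m$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          m$resolution))
  } else {
    out <- c(out, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  }
  if (nzchar(m$source)) out <- c(out, sprintf("SOURCE    %s", m$source))
  ref3 <- aa1to3(seq_to_letters(chain$ref_seq))
  nres <- length(ref3)
  ser <- 1L
  for (i in seq(1L, nres, by = 13L)) {
    blk <- ref3[i:min(i + 12L, nres)]
    out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", ser, m$chain_id, nres,
                          paste(sprintf("%-3s", blk), collapse = " ")))
    ser <- ser + 1L
  }
  if (length(chain$modres_map)) {
    for (k in names(chain$modres_map)) {
      out <- c(out, sprintf("MODRES %4s %3s %1s %4d%1s %3s  %s", m$pdb_id,
                            k, m$chain_id, 0L, " ", chain$modres_map[[k]],
                            "MODIFIED RESIDUE"))
    }
  }
  serial <- 0L
  for (i in seq_len(nrow(res))) {
    ai <- atoms[atoms$res_idx == res$res_idx[i], , drop = FALSE]
    for (j in seq_len(nrow(ai))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, fmt_atom_name(ai$name[j]),
        ifelse(nzchar(trimws(ai$alt_loc[j])), ai$alt_loc[j], " "),
        res$res_name[i], m$chain_id, res$res_num[i],
        ifelse(nzchar(trimws(res$ins_code[i])), res$ins_code[i], " "),
        ai$x[j], ai$y[j], ai$z[j], ai$occupancy[j], 0, ai$element[j]))
    }
  }
  out <- c(out, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                        res$res_name[nrow(res)], m$chain_id,
                        res$res_num[nrow(res)]),
           "END")
  out
}

#' Export chain reference sequences as FASTA text
#'
#' One entry per chain, header `pdbid_chain`, sequence `ref_seq` (any
#' `"X"` letters are preserved).
#'
#' @param chains list of [chain_record()]s.
#' @param width line-wrap width.
#' @return character vector of FASTA lines (empty for an empty list).
#' @export
extract_sequences <- function(chains, width = 60L) {
  out <- character(0)
  for (ch in chains) {
    hdr <- sprintf(">%s_%s", ch$meta$pdb_id, ch$meta$chain_id)
    s <- ch$ref_seq
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L,
                                                 nchar(s))))
  }
  out
}
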