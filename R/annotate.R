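# Per-residue annotation: 3-state secondary structure reduction and
# 3-state relative solvent accessibility classification.

.SS8_TO_SS3 <- c(H = "H", G = "H", I = "H",   # helix family
                 E = "E", B = "E",            # strand family
                 T = "C", S = "C", C = "C", " " = "C", "-" = "C")

#' Reduce 8-state secondary structure to 3 states
#'
#' H (alpha helix), G (3-10 helix) and I (pi helix) map to `H`; E
#' (strand) and B (isolated bridge) map to `E`; T (turn), S (bend) and
#' blank/loop codes map to `C` (coil). Length is preserved.
#'
#' @param ss8 per-residue 8-state string (codes `H G I E B T S`, blank or
#'   `-`; `C` is also accepted as coil).
#' @return per-residue 3-state string over `{H, E, C}`.
#' @export
ss8_to_ss3 <- function(ss8) {
  if (!nchar(ss8)) return("")
  codes <- seq_to_letters(ss8)
  out <- .SS8_TO_SS3[codes]
  if (anyNA(out)) {
    stop("unknown secondary-structure code: ",
         paste(unique(codes[is.na(out)]), collapse = ", "))
  }
  paste(out, collapse = "")
}

#' Classify relative solvent accessibility into 3 states
#'
#' `E` (exposed) when RSA is strictly greater than 0.37, `B` (buried)
#' when strictly less than 0.069, `I` (intermediate) in between --
#' including both boundary values.
#'
#' @param rsa numeric vector of RSA fractions in `[0, 1]` (values above 1
#'   are clamped with a warning).
#' @return character vector over `{E, B, I}`.
#' @export
classify_rsa <- function(rsa) {
  if (any(rsa < 0, na.rm = TRUE)) stop("negative RSA value")
  if (any(rsa > 1, na.rm = TRUE)) {
    warning("RSA value(s) above 1 clamped to 1")
    rsa <- pmin(rsa, 1)
  }
  ifelse(rsa > 0.37, "E", ifelse(rsa < 0.069, "B", "I"))
}

#' Relative solvent accessibility from absolute accessibility
#'
#' Divides the absolute accessible surface area by the residue type's
#' maximum accessibility (Rost & Sander 1994 normalization); results
#' above 1 are clamped to 1 with a warning.
#'
#' @param abs_acc absolute accessibility in square Angstrom (`>= 0`).
#' @param residue_type 1-letter residue code(s).
#' @param max_acc_table named numeric vector of per-residue maxima;
#'   override to use a different normalization.
#' @return RSA fraction(s) in `[0, 1]`.
#' @export
compute_rsa <- function(abs_acc, residue_type, max_acc_table = .MAX_ACC) {
  if (any(abs_acc < 0, na.rm = TRUE)) stop("negative absolute accessibility")
  mx <- max_acc_table[toupper(residue_type)]
  if (anyNA(mx)) {
    stop("unknown residue type: ",
         paste(unique(residue_type[is.na(mx)]), collapse = ", "))
  }
  rsa <- abs_acc / unname(mx)
  if (any(rsa > 1, na.rm = TRUE)) {
    warning("absolute accessibility exceeds the residue maximum; clamped")
    rsa <- pmin(rsa, 1)
  }
  rsa
}

#' Annotate a chain with secondary structure and accessibility classes
#'
#' The backend supplies, for every residue with coordinates, an 8-state
#' secondary-structure code and an absolute solvent accessibility (the
#' contract a DSSP-style tool or a fixture table fulfils). Reference
#' positions without coordinates are annotated `"-"`; residues whose type
#' has no accessibility normalization constant (unknown `"X"` residues)
#' get `NA` RSA and `"-"`.
#'
#' @param chain a cleaned [chain_record()] (residues numbered by
#'   reference position).
#' @param ss_backend either a function `(chain) -> data.frame` or a
#'   data.frame directly, with columns `ref_position`, `ss8`, `abs_acc`.
#' @return list of class `ss_annotation` with `ss3`, `rsa3` (strings of
#'   reference-sequence length) and `rsa` (numeric vector, `NA` where
#'   absent).
#' @export
annotate_chain <- function(chain, ss_backend) {
  tab <- if (is.function(ss_backend)) {
    tryCatch(ss_backend(chain), error = function(e) {
      stop("annotation backend failure: ", conditionMessage(e))
    })
  } else {
    ss_backend
  }
  if (is.null(tab) || !nrow(tab)) stop("annotation backend returned no rows")
  n <- nchar(chain$ref_seq)
  if (any(tab$ref_position < 1L | tab$ref_position > n)) {
    stop("backend row outside the reference sequence")
  }
  ref <- seq_to_letters(chain$ref_seq)
  ss3 <- rep("-", n)
  rsa <- rep(NA_real_, n)
  rsa3 <- rep("-", n)
  for (i in seq_len(nrow(tab))) {
    p <- tab$ref_position[i]
    ss3[p] <- ss8_to_ss3(tab$ss8[i])
    if (ref[p] %in% names(.MAX_ACC)) {
      rsa[p] <- compute_rsa(tab$abs_acc[i], ref[p])
      rsa3[p] <- classify_rsa(rsa[p])
    }
  }
  structure(list(ss3 = paste(ss3, collapse = ""), rsa = rsa,
                 rsa3 = paste(rsa3, collapse = "")),
            class = "ss_annotation")
}

#' @export
print.ss_annotation <- function(x, ...) {
  cat("seq/ss3/rsa3 annotation block:\n")
  cat("  ss3 :", x$ss3, "\n")
  cat("  rsa3:", x$rsa3, "\n")
  invisible(x)
}
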