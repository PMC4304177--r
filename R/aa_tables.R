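# Reference tables for the 20 standard amino acids.

#' @keywords internal
.AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
.AA_123 <- c(setNames(names(.AA_321), unname(.AA_321)), X = "UNK")

# Standard heavy-atom composition per residue type. Hydrogens are never
# listed: they count as beyond the standard composition and are pruned.
#' @keywords internal
.AA_HEAVY_ATOMS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  # unknown residues keep the backbone only
  UNK = c("N", "CA", "C", "O")
)

# Maximum solvent accessibility per residue (A^2), Rost & Sander (1994)
# normalization, used to convert absolute DSSP accessibility into RSA.
#' @keywords internal
.MAX_ACC <- c(
  A = 106, R = 248, N = 157, D = 163, C = 135,
  Q = 198, E = 194, G =  84, H = 184, I = 169,
  L = 164, K = 205, M = 188, F = 197, P = 136,
  S = 130, T = 142, W = 227, Y = 222, V = 142
)

#' Translate 3-letter residue codes to 1-letter codes
#'
#' Unknown (non-standard) codes translate to `"X"`.
#'
#' @param codes character vector of 3-letter residue codes.
#' @return character vector of single letters.
#' @keywords internal
aa3to1 <- function(codes) {
  out <- unname(.AA_321[toupper(codes)])
  out[is.na(out)] <- "X"
  out
}

#' @keywords internal
aa1to3 <- function(letters1) {
  out <- unname(.AA_123[toupper(letters1)])
  if (anyNA(out)) {
    stop("cannot map letters to 3-letter codes: ",
         paste(unique(letters1[is.na(out)]), collapse = ", "))
  }
  out
}

#' @keywords internal
seq_to_letters <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
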