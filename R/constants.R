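# Canonical residue alphabets and chain roles used throughout the package.

.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
          "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
          "TRP", "TYR")

.ROLES <- c("mhc_alpha", "mhc_beta", "peptide", "tcr_alpha", "tcr_beta",
            "other")

.MHC_ROLES <- c("mhc_alpha", "mhc_beta")
.TCR_ROLES <- c("tcr_alpha", "tcr_beta")

#' Convert between one- and three-letter residue codes
#'
#' Thin wrappers around the corresponding bio3d converters, restricted to
#' the 20 canonical residues.
#'
#' @param x character vector of residue codes.
#' @return character vector of converted codes.
#' @examples
#' aaOneToThree(c("A", "K"))
#' aaThreeToOne(c("ALA", "LYS"))
#' @export
aaOneToThree <- function(x) bio3d::aa123(x)

#' @rdname aaOneToThree
#' @export
aaThreeToOne <- function(x) bio3d::aa321(x)

# Default uniform background over the 20 canonical residues.
uniformBackground <- function() {
  stats::setNames(rep(1 / 20, 20), .AA1)
}

#' Normalize a substrate or antigen sequence
#'
#' Upper-cases the sequence and maps norleucine (encoded as lower-case
#' \code{n} in peptide-library substrates, where it substitutes for
#' methionine) to \code{M}. Any residue outside the supplied alphabet is
#' an error.
#'
#' @param x character vector of sequences.
#' @param alphabet allowed one-letter residues after normalization.
#' @return normalized character vector.
#' @export
normalizeSequence <- function(x, alphabet = .AA1) {
  x <- gsub("n", "M", x, fixed = TRUE)
  x <- toupper(x)
  bad <- setdiff(unique(unlist(strsplit(x, ""))), alphabet)
  if (length(bad) > 0) {
    stop("invalid residue: ", paste(bad, collapse = ", "))
  }
  x
}

.splitSeq <- function(x) strsplit(x, "")[[1]]
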