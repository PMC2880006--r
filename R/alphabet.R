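#' Canonical amino-acid alphabet
#'
#' The 20 natural amino acids in the fixed index order used throughout the
#' package for energy tables, weight matrices, marginals and Viterbi arrays:
#' alanine, cysteine, aspartic acid, glutamic acid, phenylalanine, glycine,
#' histidine, isoleucine, lysine, leucine, methionine, asparagine, proline,
#' glutamine, arginine, serine, threonine, valine, tryptophan, tyrosine
#' (alphabetical by one-letter code).
#'
#' @format `AA_ALPHABET` is a character vector of 20 one-letter codes;
#'   `AA_THREE` the matching three-letter codes.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
AA_THREE <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
              "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
              "THR", "VAL", "TRP", "TYR")

#' Normalize amino-acid codes to one-letter form
#'
#' Accepts one-letter or three-letter codes in any case and returns the
#' canonical upper-case one-letter code.
#'
#' @param x character vector of residue codes.
#' @return character vector of one-letter codes.
#' @export
aa_normalize <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- character(length(x))
  one <- nchar(x) == 1L
  out[one] <- x[one]
  idx <- match(x[!one], AA_THREE)
  out[!one] <- AA_ALPHABET[idx]
  bad <- is.na(out) | !(out %in% AA_ALPHABET)
  if (any(bad)) {
    stop("unknown residue code(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

# internal: validate a (possibly reduced) alphabet argument
check_alphabet <- function(alphabet) {
  alphabet <- aa_normalize(alphabet)
  if (anyDuplicated(alphabet)) stop("alphabet contains duplicate residues")
  if (length(alphabet) < 1L) stop("alphabet is empty")
  alphabet
}

# internal: numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
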