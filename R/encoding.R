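#' Standard amino-acid alphabet used by the integer encoding
#'
#' The twenty standard residues, alphabetical by one-letter code.  Codes
#' 1..20 follow this order; code 0 is reserved for padding and any
#' non-standard letter (B, J, O, U, X, Z, gaps).
#'
#' @format Character vector of length 20.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Encode residue letters as integer codes
#'
#' Maps each one-letter residue code to its fixed integer: `A = 1`,
#' `C = 2`, ..., `Y = 20` (alphabetical over the twenty standard amino
#' acids).  Any other character — non-standard residues, ambiguity
#' codes, gaps, `-` padding — maps to 0.  Case-insensitive.
#'
#' @param letters Character vector of single characters, or a single
#'   string which is split into characters.
#' @return Integer vector of codes in `0..20`.
#' @examples
#' encode_residue(c("A", "N", "X"))  # 1 12 0
#' encode_residue("MNKT")
#' @export
encode_residue <- function(letters) {
  if (length(letters) == 1L && nchar(letters[1]) > 1L) {
    letters <- strsplit(letters, "")[[1]]
  }
  m <- match(toupper(letters), AA_LETTERS)
  m[is.na(m)] <- 0L
  as.integer(m)
}

#' Decode integer codes back to residue letters
#'
#' Inverse of [encode_residue()] on codes 1..20; code 0 decodes to the
#' padding character `"-"`.
#'
#' @param codes Integer vector with values in `0..20`.
#' @param collapse If `TRUE`, return a single string.
#' @return Character vector of letters (or one string).
#' @export
decode_residue <- function(codes, collapse = FALSE) {
  stopifnot(all(codes >= 0L & codes <= 20L))
  out <- c("-", AA_LETTERS)[codes + 1L]
  if (collapse) paste(out, collapse = "") else out
}
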