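#' Position-relative incidence matrix (PRIM)
#'
#' 20x20 matrix whose element `A[i, j]` is the sum, over every
#' occurrence of residue j at (1-based, padding-included) window
#' position p, of the relative position `p - f_i`, where `f_i` is the
#' position of the first occurrence of residue i.  Occurrences of j
#' before the first i contribute negative terms; rows/columns of
#' residues absent from the window are zero; padding positions
#' contribute nothing (but still shift the coordinates of real
#' residues in terminal windows).
#'
#' @param window Window-like object (see [as_window_codes()]).
#' @return 20x20 numeric matrix with residue-letter dimnames.
#' @examples
#' prim("AC")["A", "C"]   # 1
#' prim("AAC")["A", "A"]  # 0 + 1
#' @export
prim <- function(window) {
  codes <- as_window_codes(window)
  if (!length(codes)) stop("window is empty")
  A <- matrix(0, 20L, 20L, dimnames = list(AA_LETTERS, AA_LETTERS))
  idx <- which(codes >= 1L)
  if (!length(idx)) return(A)
  res <- codes[idx]
  counts <- tabulate(res, nbins = 20L)
  possum <- numeric(20L)
  agg <- tapply(idx, res, sum)
  possum[as.integer(names(agg))] <- agg
  firsts <- rep(NA_real_, 20L)
  firsts[res[rev(seq_along(idx))]] <- rev(idx)  # later assigns win: first kept
  present <- which(counts > 0L)
  for (i in present) {
    A[i, present] <- possum[present] - counts[present] * firsts[i]
  }
  A
}

#' Reverse position-relative incidence matrix (RPRIM)
#'
#' PRIM computed on the reversed window: `rprim(w) = prim(rev(w))`.
#' Uncovers ordering patterns that read differently from the C- to the
#' N-terminal direction.
#'
#' @inheritParams prim
#' @return 20x20 numeric matrix.
#' @export
rprim <- function(window) {
  prim(rev(as_window_codes(window)))
}

#' Residue frequency vector
#'
#' Count of each of the twenty standard residues in the window;
#' padding is excluded, so the counts sum to the number of real
#' residues.
#'
#' @inheritParams prim
#' @return Named numeric vector of length 20.
#' @export
frequency_vector <- function(window) {
  codes <- as_window_codes(window)
  stats::setNames(as.numeric(tabulate(codes[codes >= 1L], nbins = 20L)),
                  AA_LETTERS)
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For each residue, the sum of the 1-based window positions at which
#' it occurs (0 for absent residues).  Padding positions contribute
#' nothing.
#'
#' @inheritParams prim
#' @return Named numeric vector of length 20.
#' @examples
#' aapiv("AAC")[c("A", "C")]  # 3 3
#' @export
aapiv <- function(window) {
  codes <- as_window_codes(window)
  out <- stats::setNames(numeric(20L), AA_LETTERS)
  idx <- which(codes >= 1L)
  if (!length(idx)) return(out)
  agg <- tapply(idx, codes[idx], sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Reverse accumulative absolute position incidence vector (RAAPIV)
#'
#' AAPIV of the reversed window: `raapiv(w) = aapiv(rev(w))`.  On a
#' pad-free window of length k the exact identity
#' `aapiv + raapiv = (k + 1) * frequency_vector` holds.
#'
#' @inheritParams prim
#' @return Named numeric vector of length 20.
#' @export
raapiv <- function(window) {
  aapiv(rev(as_window_codes(window)))
}
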