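#' Site vicinity window
#'
#' A fixed-length integer-encoded peptide subsequence centred on a
#' candidate modification site, together with the 1-based position of
#' the site in its source protein and an optional class label.
#'
#' @param codes Integer vector of residue codes (see [encode_residue()]).
#' @param site_position 1-based position of the central residue in the
#'   source protein, or `NA`.
#' @param label `1L` (positive), `0L` (negative) or `NA` (unknown).
#' @return An object of class `site_window`.
#' @export
site_window <- function(codes, site_position = NA_integer_,
                        label = NA_integer_) {
  codes <- as.integer(codes)
  if (length(codes) %% 2L == 0L) {
    stop("a site window must have odd length (2r + 1)")
  }
  if (any(codes < 0L | codes > 20L)) {
    stop("residue codes must lie in 0..20")
  }
  structure(list(codes = codes,
                 site_position = as.integer(site_position),
                 label = as.integer(label)),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s  site=%s  label=%s\n",
              decode_residue(x$codes, collapse = TRUE),
              x$site_position, x$label))
  invisible(x)
}

#' Coerce a window-like object to its integer code vector
#'
#' Accepts a `site_window`, a character string of residue letters
#' (with `-` for padding), a character vector of single letters, or an
#' integer code vector, and returns the integer codes.
#'
#' @param x Window-like object.
#' @return Integer vector of codes in `0..20`.
#' @export
as_window_codes <- function(x) {
  if (inherits(x, "site_window")) return(x$codes)
  if (is.character(x)) return(encode_residue(x))
  if (is.numeric(x)) {
    codes <- as.integer(x)
    if (any(codes < 0L | codes > 20L)) stop("codes must lie in 0..20")
    return(codes)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a site window")
}

#' Enumerate candidate N-glycosylation sites
#'
#' Every asparagine (N) position in a protein sequence is a candidate
#' site for N-linked glycosylation.
#'
#' @param sequence Protein sequence string (or a `ProteinRecord`-style
#'   list with a `sequence` element).
#' @return Integer vector of 1-based asparagine positions, ascending.
#' @examples
#' enumerate_candidate_sites("MNKT")  # 2
#' @export
enumerate_candidate_sites <- function(sequence) {
  if (is.list(sequence)) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(integer(0))
  which(strsplit(toupper(sequence), "")[[1]] == "N")
}

#' Extract a site vicinity window around a candidate site
#'
#' Returns the `2r + 1` residues centred on `site`, integer encoded.
#' Positions falling outside the sequence (windows near the termini)
#' are filled with the padding code 0.
#'
#' @param sequence Protein sequence string (or a list with `sequence`).
#' @param site 1-based position of the candidate site.
#' @param r Number of flanking residues on each side (default 20,
#'   giving the 41-mer used throughout).
#' @param label Optional class label stored on the window.
#' @return A [site_window()] of length `2r + 1`.
#' @examples
#' extract_window("MNKT", site = 2, r = 2)
#' @export
extract_window <- function(sequence, site, r = 20L, label = NA_integer_) {
  if (is.list(sequence)) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  site <- as.integer(site)
  r <- as.integer(r)
  if (is.na(site) || site < 1L || site > n) {
    stop("site ", site, " is outside the sequence (length ", n, ")")
  }
  codes <- integer(2L * r + 1L)
  pos <- (site - r):(site + r)
  inside <- pos >= 1L & pos <= n
  letters <- strsplit(toupper(sequence), "")[[1]]
  codes[inside] <- encode_residue(letters[pos[inside]])
  site_window(codes, site_position = site, label = label)
}

#' Extract labelled windows for every candidate site of a protein
#'
#' Convenience wrapper: enumerates asparagine positions and extracts a
#' window for each, returning a window table (see
#' [read_window_table()] for the format).
#'
#' @param id Protein identifier used to build window ids.
#' @param sequence Protein sequence string.
#' @param r Flank size (default 20).
#' @return Data frame with columns `id`, `window`, `label` (label `NA`).
#' @export
protein_windows <- function(id, sequence, r = 20L) {
  sites <- enumerate_candidate_sites(sequence)
  wins <- vapply(sites, function(s) {
    decode_residue(extract_window(sequence, s, r)$codes, collapse = TRUE)
  }, character(1))
  data.frame(id = if (length(sites)) paste0(id, "_", sites) else character(0),
             window = wins,
             label = rep(NA_integer_, length(sites)),
             stringsAsFactors = FALSE)
}
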