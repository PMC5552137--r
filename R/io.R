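#' Read protein records from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()].  Identifiers are
#' the first whitespace-delimited token of each header; sequences are
#' upper-cased.
#'
#' @param path Path to a FASTA file (multi-record, wrapped lines).
#' @return Data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  data.frame(id = unname(ids),
             sequence = toupper(unname(as.character(aa))),
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read a labelled window table
#'
#' Window tables are UTF-8 tab-separated text with a header line and
#' three columns: `id`, `window` (a fixed-width residue string, `-`
#' allowed for terminal padding) and `label` (`1` positive, `0`
#' negative; empty or `NA` for unknown).  They stand in for bulk
#' site-window exports from annotation databases.
#'
#' @param path Path to the TSV file.
#' @param width Required window width (default 41).  Rows with a
#'   different width raise an error naming the offending line.
#' @return Data frame with columns `id` (character), `window`
#'   (character) and `label` (integer).
#' @export
read_window_table <- function(path, width = 41L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          na.strings = c("NA", ""),
                          quote = "", comment.char = "")
  need <- c("id", "window", "label")
  if (!all(need %in% names(df))) {
    stop("window table must have header columns id, window, label")
  }
  bad <- which(nchar(df$window) != width)
  if (length(bad)) {
    stop(sprintf("window on line %d has %d letters, expected %d",
                 bad[1] + 1L, nchar(df$window[bad[1]]), width))
  }
  lab <- df$label
  ok <- is.na(lab) | lab %in% c("0", "1")
  if (!all(ok)) {
    stop(sprintf("label on line %d is '%s', expected 0 or 1",
                 which(!ok)[1] + 1L, lab[which(!ok)[1]]))
  }
  data.frame(id = df$id,
             window = toupper(df$window),
             label = as.integer(lab),
             stringsAsFactors = FALSE)
}

#' Write a labelled window table
#'
#' @param windows Data frame with columns `id`, `window`, `label`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_window_table()] for the format.
#' @export
write_window_table <- function(windows, path) {
  stopifnot(all(c("id", "window", "label") %in% names(windows)))
  utils::write.table(windows[, c("id", "window", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a feature matrix with ids and labels
#'
#' One row per window: `id`, `label`, then the 173 feature columns.
#'
#' @param features Numeric matrix (rows = windows) as produced by
#'   [feature_matrix()].
#' @param windows The window table the features came from.
#' @param path Output path (TSV).
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, windows, path) {
  stopifnot(nrow(features) == nrow(windows))
  df <- data.frame(id = windows$id, label = windows$label,
                   features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
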