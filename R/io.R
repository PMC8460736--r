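#' Read proteins from FASTA
#'
#' Reads a multi-record amino-acid FASTA file, keeps the first whitespace
#' token of each header as the accession, and maps nonstandard residues to
#' the wildcard `Z` (with a warning naming the letters replaced).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort("FASTA contains no records.", class = "kptm_empty_input")
  tibble(id = sub("\\s.*$", "", names(seqs)),
         sequence = sanitize_sequence(unname(as.character(seqs))))
}

#' Write proteins to FASTA
#'
#' @param proteins Data frame with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  x <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a PTM annotation table
#'
#' Tab-separated with columns `protein_id`, `position` (1-based) and
#' `ptm_type`; lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three columns.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_id = readr::col_character(),
                    position = readr::col_integer(),
                    ptm_type = readr::col_character()))
}

#' @rdname read_annotations
#' @param annotations Data frame with columns `protein_id`, `position`,
#'   `ptm_type`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Read / write a peptide benchmark dataset as TSV
#'
#' Columns: `window`, `labels` (comma-joined, empty for Non-K-PTM),
#' `protein_id`, `position`.
#'
#' @param data A `kptm_dataset`.
#' @param path Path to the TSV file.
#' @param zeta Half-window size to record on read (inferred from the window
#'   length when `NULL`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `kptm_dataset`.
#' @export
write_dataset <- function(data, path) {
  readr::write_tsv(data[c("window", "labels", "protein_id", "position")], path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, zeta = NULL) {
  ds <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          window = readr::col_character(),
                          labels = readr::col_character(),
                          protein_id = readr::col_character(),
                          position = readr::col_integer()))
  ds$labels[is.na(ds$labels)] <- ""
  if (is.null(zeta)) zeta <- (nchar(ds$window[1]) - 1L) %/% 2L
  new_kptm_dataset(ds, zeta)
}
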