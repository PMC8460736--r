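#' The 21-letter residue alphabet and the K-PTM label universe
#'
#' All encoders work over a 21-symbol alphabet: the 20 standard amino acids
#' plus `"Z"`, a reserved wildcard used both for nonstandard residues mapped
#' on load (B, J, O, U, X and the ambiguity code Z itself) and, conceptually,
#' for anything outside the standard alphabet. The five lysine
#' post-translational modification (K-PTM) types handled by the package are
#' acetylation, crotonylation, methylation, succinylation and glutarylation.
#'
#' @return `kptm_alphabet()` returns a length-21 character vector in the
#'   fixed order `"ACDEFGHIKLMNPQRSTVWYZ"`; `kptm_labels()` returns the five
#'   PTM-type names in their canonical order.
#' @examples
#' kptm_alphabet()
#' kptm_labels()
#' @export
kptm_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWYZ", "")[[1]]
}

#' @rdname kptm_alphabet
#' @export
kptm_labels <- function() {
  c("acetylation", "crotonylation", "methylation", "succinylation",
    "glutarylation")
}

# Explicit null label used by the multi-label metrics so that an unmodified
# sample is never an empty set (see multilabel_metrics()).
kptm_null_label <- function() "Non-K-PTM"

#' Map a raw amino-acid sequence onto the 21-letter alphabet
#'
#' Uppercases the input and replaces every character outside the 20 standard
#' amino acids with the wildcard `"Z"`, warning once per call about which
#' letters were replaced. Used by [read_proteins()] and available directly
#' for sequences assembled in code.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param quiet Suppress the replacement warning.
#' @return Character vector of the same length over the 21-letter alphabet.
#' @examples
#' sanitize_sequence("mkvXub")
#' @export
sanitize_sequence <- function(sequence, quiet = FALSE) {
  sequence <- toupper(sequence)
  standard <- setdiff(kptm_alphabet(), "Z")
  bad <- setdiff(unique(strsplit(paste(sequence, collapse = ""), "")[[1]]),
                 kptm_alphabet())
  if (length(bad) > 0) {
    if (!quiet) {
      warn(paste0("Nonstandard residue(s) mapped to wildcard 'Z': ",
                  paste(sort(bad), collapse = ", ")))
    }
    sequence <- gsub(paste0("[^", paste(standard, collapse = ""), "]"), "Z",
                     sequence)
  }
  sequence
}

# Windows (equal-length strings) -> integer matrix of alphabet indices,
# n_windows x window_length, values in 1..21.
windows_to_index <- function(windows) {
  if (length(windows) == 0) abort("No windows supplied.", class = "kptm_empty_input")
  len <- unique(nchar(windows))
  if (length(len) != 1) {
    abort("All windows must have equal length.", class = "kptm_shape_error")
  }
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = length(windows), ncol = len, byrow = TRUE)
  idx <- match(chars, kptm_alphabet())
  if (anyNA(idx)) {
    abort("Window contains a residue outside the 21-letter alphabet.",
          class = "kptm_alphabet_error")
  }
  matrix(idx, nrow = length(windows), ncol = len)
}
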