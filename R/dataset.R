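#' Extract a fixed-length peptide window centred on a lysine
#'
#' Cuts the `2 * zeta + 1` residues around a 1-based position whose residue
#' must be `K`. When the window overruns a protein terminus, the missing
#' flank is filled by repeating that terminus' residue, so every candidate
#' site yields an equal-length window.
#'
#' @param sequence Protein sequence (single string over the 21-letter
#'   alphabet; see [sanitize_sequence()]).
#' @param position 1-based residue index of the centre lysine.
#' @param zeta Half-window size; the default 24 gives 49-residue windows.
#' @return A single string of length `2 * zeta + 1` with `K` at its centre.
#' @examples
#' extract_window("AAAAKCCCC", 5, zeta = 2)
#' extract_window("KCD", 1, zeta = 2) # left flank filled with terminal 'K'
#' @export
extract_window <- function(sequence, position, zeta = 24L) {
  stopifnot(length(sequence) == 1L, length(position) == 1L, zeta >= 1L)
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    abort(sprintf("Position %d outside sequence of length %d.", position, n),
          class = "kptm_index_error")
  }
  if (substr(sequence, position, position) != "K") {
    abort(sprintf("Residue at position %d is '%s', not the required 'K'.",
                  position, substr(sequence, position, position)),
          class = "kptm_center_residue_error")
  }
  left <- substr(sequence, max(1L, position - zeta), position - 1L)
  right <- substr(sequence, position + 1L, min(n, position + zeta))
  left_fill <- strrep(substr(sequence, 1L, 1L), zeta - nchar(left))
  right_fill <- strrep(substr(sequence, n, n), zeta - nchar(right))
  paste0(left_fill, left, "K", right, right_fill)
}

#' Build the multi-label peptide benchmark from proteins and annotations
#'
#' Every lysine in every protein yields one candidate window; its label set
#' is the union of the PTM types annotated at that (protein, position), and
#' an empty set marks a Non-K-PTM (negative) sample. Exact-duplicate windows
#' are collapsed to a single sample carrying the union of their labels, so a
#' window observed modified anywhere counts as modified.
#'
#' @param proteins Data frame with columns `id`, `sequence` (see
#'   [read_proteins()]).
#' @param annotations Data frame with columns `protein_id`, `position`,
#'   `ptm_type`. Annotations whose position is out of range, whose residue
#'   is not `K`, or whose type is unknown are dropped with a warning.
#' @param zeta Half-window size (default 24).
#' @return A `kptm_dataset`: a tibble with columns `window`, `labels`
#'   (comma-joined PTM names in canonical order, `""` for Non-K-PTM),
#'   `protein_id`, `position` (the first origin of each deduplicated
#'   window), with the half-window size in `attr(, "zeta")`. Use
#'   [label_multiplicity()] for the histogram of labels per sample and
#'   [label_matrix()] for the sample-by-PTM logical matrix.
#' @examples
#' prot <- tibble::tibble(id = "P1", sequence = "AAKAAKAA")
#' ann <- tibble::tibble(protein_id = "P1", position = 3,
#'                       ptm_type = "acetylation")
#' build_benchmark(prot, ann, zeta = 2)
#' @export
build_benchmark <- function(proteins, annotations, zeta = 24L) {
  if (!is.data.frame(proteins) || nrow(proteins) == 0) {
    abort("`proteins` is empty.", class = "kptm_empty_input")
  }
  if (is.null(annotations)) {
    annotations <- tibble(protein_id = character(), position = integer(),
                          ptm_type = character())
  }
  annotations <- check_annotations(proteins, annotations)

  sites <- purrr::pmap_dfr(proteins[c("id", "sequence")], function(id, sequence) {
    pos <- which(strsplit(sequence, "")[[1]] == "K")
    if (length(pos) == 0) return(NULL)
    tibble(protein_id = id, position = pos,
           window = vapply(pos, function(p) extract_window(sequence, p, zeta),
                           character(1)))
  })
  if (nrow(sites) == 0) {
    ds <- tibble(window = character(), labels = character(),
                 protein_id = character(), position = integer())
    return(new_kptm_dataset(ds, zeta))
  }

  ann <- annotations |>
    dplyr::group_by(.data$protein_id, .data$position) |>
    dplyr::summarise(labels = join_labels(.data$ptm_type), .groups = "drop")
  ds <- sites |>
    dplyr::left_join(ann, by = c("protein_id", "position")) |>
    dplyr::mutate(labels = dplyr::coalesce(.data$labels, "")) |>
    # dedup: union labels across identical windows, keep first origin
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      labels = join_labels(unlist(split_labels(.data$labels))),
      protein_id = .data$protein_id[1],
      position = .data$position[1],
      .groups = "drop") |>
    dplyr::select("window", "labels", "protein_id", "position") |>
    dplyr::arrange(.data$protein_id, .data$position)
  new_kptm_dataset(ds, zeta)
}

new_kptm_dataset <- function(ds, zeta) {
  ds <- as_tibble(ds)
  attr(ds, "zeta") <- as.integer(zeta)
  class(ds) <- c("kptm_dataset", class(ds))
  ds
}

#' @export
`[.kptm_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "window" %in% names(out)) {
    attr(out, "zeta") <- attr(x, "zeta")
    class(out) <- unique(c("kptm_dataset", class(out)))
  }
  out
}

check_annotations <- function(proteins, annotations) {
  need <- c("protein_id", "position", "ptm_type")
  if (!all(need %in% names(annotations))) {
    abort("`annotations` needs columns protein_id, position, ptm_type.",
          class = "kptm_shape_error")
  }
  ann <- as_tibble(annotations)
  ann$position <- as.integer(ann$position)
  ann <- dplyr::left_join(ann, proteins[c("id", "sequence")],
                          by = c(protein_id = "id"))
  residue <- ifelse(is.na(ann$sequence) | ann$position < 1L |
                      ann$position > nchar(ann$sequence), NA_character_,
                    substr(ann$sequence, ann$position, ann$position))
  reason <- dplyr::case_when(
    is.na(ann$sequence) ~ "unknown protein",
    is.na(residue) ~ "position out of range",
    residue != "K" ~ paste0("residue is '", residue, "', not K"),
    !ann$ptm_type %in% kptm_labels() ~ paste0("unknown PTM type '", ann$ptm_type, "'"),
    TRUE ~ NA_character_
  )
  bad <- !is.na(reason)
  if (any(bad)) {
    warn(sprintf("Dropped %d annotation(s): %s.", sum(bad),
                 paste(unique(reason[bad]), collapse = "; ")))
  }
  ann[!bad, need]
}

join_labels <- function(types) {
  types <- intersect(kptm_labels(), unique(types)) # canonical order
  paste(types, collapse = ",")
}

split_labels <- function(labels) {
  strsplit(as.character(labels), ",", fixed = TRUE)
}

#' Per-sample label count histogram
#'
#' Counts how many samples carry 0 (Non-K-PTM), 1, 2, 3, 4 or 5 PTM labels.
#'
#' @param data A `kptm_dataset` or any data frame with a `labels` column.
#' @return A tibble with columns `n_labels` (0..5) and `n_samples`.
#' @export
label_multiplicity <- function(data) {
  k <- lengths(split_labels(data$labels))
  tibble(n_labels = 0:5,
         n_samples = vapply(0:5, function(i) sum(k == i), integer(1)))
}

#' Sample-by-PTM label indicator matrix
#'
#' @param data A data frame with a `labels` column (comma-joined PTM names).
#' @return Logical matrix, one row per sample, one column per PTM type.
#' @export
label_matrix <- function(data) {
  sets <- split_labels(data$labels)
  out <- vapply(kptm_labels(), function(l) {
    vapply(sets, function(s) l %in% s, logical(1))
  }, logical(nrow(data)))
  matrix(out, nrow = nrow(data), dimnames = list(NULL, kptm_labels()))
}

#' Positive/negative view of the benchmark for one PTM type
#'
#' Splits a dataset into the samples whose label set contains `ptm_type`
#' (positives) and all remaining samples (negatives); together they
#' partition the dataset, and a multi-label sample is a positive in the
#' view of each of its labels.
#'
#' @param data A `kptm_dataset` (typically post-undersampling).
#' @param ptm_type One of [kptm_labels()].
#' @return A list with tibbles `positives` and `negatives`.
#' @export
per_ptm_view <- function(data, ptm_type) {
  if (!ptm_type %in% kptm_labels()) {
    abort(sprintf("Unknown PTM type '%s'.", ptm_type), class = "kptm_key_error")
  }
  pos <- label_matrix(data)[, ptm_type]
  list(positives = data[pos, , drop = FALSE],
       negatives = data[!pos, , drop = FALSE])
}

#' @exportS3Method generics::glance
glance.kptm_dataset <- function(x, ...) {
  lm <- label_matrix(x)
  tibble(n_samples = nrow(x),
         n_positive = sum(x$labels != ""),
         n_negative = sum(x$labels == ""),
         zeta = attr(x, "zeta") %||% NA_integer_,
         !!!as.list(colSums(lm)))
}
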