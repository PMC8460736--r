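#' Fit the sequence-coupling probability model
#'
#' Estimates, separately from the modified (positive) and unmodified
#' (negative) training windows, position-specific probabilities of the
#' residue observed at each non-centre offset. Offsets `-zeta..-2` are
#' conditional on the neighbouring residue one step toward the centre
#' (offset `j + 1`); offsets `+2..+zeta` condition on offset `j - 1`;
#' offsets -1 and +1, which neighbour the invariant centre `K`, carry
#' unconditional position-specific probabilities. A pseudocount is added to
#' every cell before normalisation so unseen (residue, context) pairs keep
#' small nonzero probability.
#'
#' @param positives,negatives Data frames with a `window` column, or
#'   character vectors of equal-length K-centred windows.
#' @param pseudocount Additive smoothing constant (default `1e-4`).
#' @return A `coupling_model`: per-offset probability tables for both
#'   classes (`21 x 21` matrices `p[residue, context]` for conditional
#'   offsets, length-21 vectors at offsets -1/+1), plus `zeta`,
#'   `pseudocount` and the alphabet.
#' @seealso [encode_coupling()], [write_coupling()]
#' @export
fit_coupling <- function(positives, negatives, pseudocount = 1e-4) {
  pos <- as_windows(positives)
  neg <- as_windows(negatives)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Both positive and negative training windows are required.",
          class = "kptm_empty_input")
  }
  if (unique(nchar(pos)) != unique(nchar(neg))) {
    abort("Positive and negative windows differ in length.",
          class = "kptm_shape_error")
  }
  len <- nchar(pos[1])
  zeta <- (len - 1L) %/% 2L
  model <- list(zeta = zeta, pseudocount = pseudocount,
                alphabet = paste(kptm_alphabet(), collapse = ""),
                pos = class_tables(pos, zeta, pseudocount),
                neg = class_tables(neg, zeta, pseudocount))
  structure(model, class = "coupling_model")
}

# offset j (non-zero, |j| <= zeta) -> column in the window matrix
offset_col <- function(j, zeta) j + zeta + 1L

coupling_offsets <- function(zeta) setdiff(-zeta:zeta, 0L)

class_tables <- function(windows, zeta, eps) {
  idx <- windows_to_index(windows)
  n <- nrow(idx)
  tabs <- list()
  for (j in coupling_offsets(zeta)) {
    a <- idx[, offset_col(j, zeta)]
    if (abs(j) == 1L) {
      cnt <- tabulate(a, nbins = 21L)
      tabs[[as.character(j)]] <- (cnt + eps) / (n + 21 * eps)
    } else {
      ctx_off <- if (j < 0) j + 1L else j - 1L
      b <- idx[, offset_col(ctx_off, zeta)]
      # rows: residue at j; cols: context residue one step toward the centre
      cnt <- matrix(tabulate(a + (b - 1L) * 21L, nbins = 441L), 21L, 21L)
      p <- sweep(cnt + eps, 2L, colSums(cnt) + 21 * eps, "/")
      tabs[[as.character(j)]] <- p
    }
  }
  tabs
}

#' Encode windows with sequence-coupling differences
#'
#' For each non-centre offset, emits the positive-class probability of the
#' observed residue (conditional per [fit_coupling()]) minus the
#' negative-class probability, yielding `2 * zeta` features in `[-1, 1]`
#' (48 for `zeta = 24`). Identical positive and negative models give the
#' all-zero vector; swapping the classes negates every component.
#'
#' @inheritParams encode_aaf
#' @param model A `coupling_model` from [fit_coupling()]; its `zeta` must
#'   match the window length.
#' @return A tibble of features named `coupling:p{offset}`.
#' @export
encode_coupling <- function(data, model) {
  windows <- as_windows(data)
  stopifnot(inherits(model, "coupling_model"))
  idx <- windows_to_index(windows)
  zeta <- model$zeta
  if (ncol(idx) != 2L * zeta + 1L) {
    abort(sprintf("Window length %d does not match model zeta = %d.",
                  ncol(idx), zeta), class = "kptm_shape_error")
  }
  offs <- coupling_offsets(zeta)
  out <- matrix(0, nrow = nrow(idx), ncol = length(offs))
  for (m in seq_along(offs)) {
    j <- offs[m]
    a <- idx[, offset_col(j, zeta)]
    if (abs(j) == 1L) {
      out[, m] <- model$pos[[as.character(j)]][a] -
        model$neg[[as.character(j)]][a]
    } else {
      ctx_off <- if (j < 0) j + 1L else j - 1L
      b <- idx[, offset_col(ctx_off, zeta)]
      out[, m] <- model$pos[[as.character(j)]][cbind(a, b)] -
        model$neg[[as.character(j)]][cbind(a, b)]
    }
  }
  colnames(out) <- paste0("coupling:p", offs)
  as_tibble(out)
}

#' Serialize a coupling model to JSON
#'
#' @param model A `coupling_model`.
#' @param path Output path.
#' @return `path` (`write_coupling`) or a `coupling_model`
#'   (`read_coupling`).
#' @export
write_coupling <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_coupling
#' @export
read_coupling <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$zeta <- as.integer(raw$zeta)
  structure(raw, class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf(
    "<coupling_model> zeta = %d (%d offsets), pseudocount = %g\n",
    x$zeta, 2 * x$zeta, x$pseudocount))
  invisible(x)
}
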