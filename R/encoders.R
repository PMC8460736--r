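#' One-hot binary encoding of peptide windows
#'
#' Each residue becomes a 21-bit one-hot vector over the alphabet order
#' `"ACDEFGHIKLMNPQRSTVWYZ"`; vectors are concatenated position-major,
#' giving `21 * (2 * zeta + 1)` features (1029 for `zeta = 24`).
#'
#' @inheritParams encode_aaf
#' @return A tibble of 0/1 features, columns named `be:p{offset}:{residue}`.
#' @examples
#' encode_binary("AKG")[, 1:5]
#' @export
encode_binary <- function(data) {
  windows <- as_windows(data)
  idx <- windows_to_index(windows)
  len <- ncol(idx)
  zeta <- (len - 1L) %/% 2L
  out <- matrix(0, nrow = nrow(idx), ncol = 21L * len)
  for (p in seq_len(len)) {
    out[cbind(seq_len(nrow(idx)), (p - 1L) * 21L + idx[, p])] <- 1
  }
  offs <- seq_len(len) - zeta - 1L
  colnames(out) <- as.vector(vapply(
    offs, function(o) paste0("be:p", o, ":", kptm_alphabet()), character(21)))
  as_tibble(out)
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing `k`, counts every ordered residue pair `(a, b)` at
#' positions `(i, i + k + 1)` within the window and divides by the number of
#' such pairs, `N_total(k) = (2 * zeta + 1) - k - 1`, so each 441-column
#' block (21 x 21 ordered pairs) sums to exactly 1. Blocks are concatenated
#' in ascending `k`; the default `k = 0..4` on 49-residue windows gives
#' 2205 features.
#'
#' @inheritParams encode_aaf
#' @param k_values Integer vector of spacings; every `k` must satisfy
#'   `k <= 2 * zeta - 1`.
#' @return A tibble of pair frequencies, columns named
#'   `cksaap:k{k}:{a}{b}`.
#' @examples
#' rowSums(encode_cksaap("AAKCC", k_values = 0))
#' @export
encode_cksaap <- function(data, k_values = 0:4) {
  windows <- as_windows(data)
  idx <- windows_to_index(windows)
  len <- ncol(idx)
  k_values <- sort(unique(as.integer(k_values)))
  if (max(k_values) > len - 2L) {
    abort(sprintf("k = %d leaves no pairs in windows of length %d.",
                  max(k_values), len),
          class = "kptm_window_too_short")
  }
  alpha <- kptm_alphabet()
  pair_names <- paste0(rep(alpha, each = 21L), rep(alpha, times = 21L))
  n <- nrow(idx)
  blocks <- lapply(k_values, function(k) {
    counts <- matrix(0, nrow = n, ncol = 441L)
    for (i in seq_len(len - k - 1L)) {
      pid <- (idx[, i] - 1L) * 21L + idx[, i + k + 1L]
      counts[cbind(seq_len(n), pid)] <- counts[cbind(seq_len(n), pid)] + 1
    }
    counts <- counts / (len - k - 1L)
    colnames(counts) <- paste0("cksaap:k", k, ":", pair_names)
    counts
  })
  as_tibble(do.call(cbind, blocks))
}
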