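# Amino-acid factor (AAF) scores: the five multivariate factors of
# Atchley, Zhao, Fernandes & Drueke (PNAS 2005, 102:6395-6400), derived by
# factor analysis of ~500 AAIndex physicochemical properties. Factor
# interpretation: f1 polarity/accessibility/hydrophobicity, f2 secondary
# structure propensity, f3 molecular size/volume, f4 codon composition /
# diversity, f5 electrostatic charge. Version: Atchley 2005 Table 2.
# Wildcard 'Z' carries the all-zero vector by convention.
.aaf_values <- matrix(c(
  # f1      f2      f3      f4      f5
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512,  # Y
   0.000,  0.000,  0.000,  0.000,  0.000   # Z (wildcard)
), nrow = 21, ncol = 5, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWYZ", "")[[1]],
                  c("polarity", "secondary_structure", "molecular_volume",
                    "codon_diversity", "charge")))

#' Amino-acid factor table
#'
#' The five multivariate physicochemical factor scores per residue
#' (polarity, secondary-structure propensity, molecular volume, codon
#' diversity, electrostatic charge) used by [encode_aaf()]. The scores are
#' the Atchley et al. (2005) factor solution over the AAIndex property
#' collection; the wildcard residue `"Z"` maps to the all-zero vector.
#'
#' @return A 21-row tibble with columns `residue` and the five factor scores.
#' @examples
#' aaf_table()
#' @export
aaf_table <- function() {
  tibble::as_tibble(.aaf_values, rownames = "residue")
}

#' Encode peptide windows with amino-acid factors
#'
#' Each residue contributes its five factor scores; scores are concatenated
#' position-major, giving `5 * (2 * zeta + 1)` features per window (245 for
#' the default half-window `zeta = 24`).
#'
#' @param data A data frame with a `window` column (equal-length K-centred
#'   peptide windows over the 21-letter alphabet), or a character vector of
#'   windows.
#' @return A tibble of numeric features, one row per window, columns named
#'   `aaf:p{offset}:{factor}` for offsets `-zeta..+zeta`.
#' @seealso [encode_binary()], [encode_cksaap()], [encode_coupling()],
#'   [encode_ensemble()]
#' @examples
#' encode_aaf(c("AAKCC", "KKKKK"))
#' @export
encode_aaf <- function(data) {
  windows <- as_windows(data)
  idx <- windows_to_index(windows)
  len <- ncol(idx)
  zeta <- (len - 1L) %/% 2L
  out <- matrix(0, nrow = nrow(idx), ncol = 5L * len)
  for (p in seq_len(len)) {
    out[, (p - 1L) * 5L + 1:5] <- .aaf_values[idx[, p], , drop = FALSE]
  }
  offs <- seq_len(len) - zeta - 1L
  colnames(out) <- as.vector(vapply(
    offs, function(o) paste0("aaf:p", o, ":", colnames(.aaf_values)),
    character(5)))
  as_tibble(out)
}

# Accept either a data frame with a `window` column or a bare character
# vector; every encoder goes through this.
as_windows <- function(data) {
  if (is.data.frame(data)) {
    if (!"window" %in% names(data)) {
      abort("`data` must contain a `window` column.", class = "kptm_shape_error")
    }
    as.character(data$window)
  } else if (is.character(data)) {
    data
  } else {
    abort("`data` must be a data frame or character vector of windows.",
          class = "kptm_shape_error")
  }
}
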