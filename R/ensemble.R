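#' Serial ensemble of the four window encoders
#'
#' Concatenates, in order, the amino-acid-factor, one-hot binary, k-spaced
#' pair and sequence-coupling encodings of each window. With the defaults
#' (`zeta = 24`, `k = 0..4`, all encoders on) the ensemble has
#' `49*5 + 49*21 + 441*5 + 48 = 3527` columns. Standardisation parameters,
#' when requested, are learned from the supplied windows (a training
#' subset) and returned so the identical transform can be applied to any
#' other subset via [apply_scaler()].
#'
#' @inheritParams encode_aaf
#' @param coupling_model A fitted [fit_coupling()] model (required when the
#'   `coupling` encoder is on). Fit it on training data only.
#' @param encoders Character subset of
#'   `c("aaf", "binary", "cksaap", "coupling")`.
#' @param k_values CKSAAP spacings (default `0:4`).
#' @param standardize Z-score each column using mean/sd learned from these
#'   rows; zero-variance columns keep scale 1 (with a warning).
#' @return A tibble of features; when `standardize = TRUE` the learned
#'   parameters are attached as `attr(, "scaler")` (a tibble with columns
#'   `feature`, `mean`, `sd`).
#' @export
encode_ensemble <- function(data, coupling_model = NULL,
                            encoders = c("aaf", "binary", "cksaap", "coupling"),
                            k_values = 0:4, standardize = FALSE) {
  encoders <- match.arg(encoders, several.ok = TRUE)
  windows <- as_windows(data)
  blocks <- list()
  if ("aaf" %in% encoders) blocks$aaf <- encode_aaf(windows)
  if ("binary" %in% encoders) blocks$binary <- encode_binary(windows)
  if ("cksaap" %in% encoders) blocks$cksaap <- encode_cksaap(windows, k_values)
  if ("coupling" %in% encoders) {
    if (is.null(coupling_model)) {
      abort("The coupling encoder needs a fitted `coupling_model`.",
            class = "kptm_shape_error")
    }
    blocks$coupling <- encode_coupling(windows, coupling_model)
  }
  out <- dplyr::bind_cols(blocks, .name_repair = "minimal")
  if (standardize) {
    scaler <- fit_scaler(out)
    out <- apply_scaler(out, scaler)
    attr(out, "scaler") <- scaler
  }
  out
}

#' Column-wise standardisation parameters
#'
#' @param features A data frame of numeric features (training rows).
#' @return A tibble with columns `feature`, `mean`, `sd`; zero-variance
#'   columns get `sd = 1` so they map to constant zero, with a warning.
#' @export
fit_scaler <- function(features) {
  m <- as.matrix(features)
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    warn(sprintf("%d zero-variance column(s); their scale is set to 1.",
                 sum(zero)))
    s[zero] <- 1
  }
  tibble(feature = colnames(m), mean = unname(mu), sd = unname(s))
}

#' @rdname fit_scaler
#' @param scaler A tibble from `fit_scaler()`; its features must match the
#'   columns of `features` in order.
#' @export
apply_scaler <- function(features, scaler) {
  if (!identical(colnames(features), scaler$feature)) {
    abort("Scaler features do not match the feature columns.",
          class = "kptm_shape_error")
  }
  m <- sweep(sweep(as.matrix(features), 2L, scaler$mean, "-"),
             2L, scaler$sd, "/")
  as_tibble(m)
}
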