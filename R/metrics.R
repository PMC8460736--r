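#' Chou's five multi-label evaluation metrics
#'
#' For true label sets `Y_i` and predicted sets `Y'_i` over `N` samples:
#' aiming is the mean of `|Y ∩ Y'| / |Y'|` (precision of predicted labels),
#' coverage the mean of `|Y ∩ Y'| / |Y|` (recall of true labels), accuracy
#' the mean Jaccard `|Y ∩ Y'| / |Y ∪ Y'|`, absolute-true the fraction of
#' samples predicted exactly right, and absolute-false (Hamming loss) the
#' mean of `(|Y ∪ Y'| - |Y ∩ Y'|) / L`.
#'
#' Under the default `"null"` convention an unmodified sample is
#' represented by an explicit `Non-K-PTM` label, so no set is ever empty
#' and the label universe has `L = 6` members. The `"strict"` convention
#' keeps empty sets with `L = 5` and defines `0/0 := 1` in aiming and
#' coverage.
#'
#' @param data Optional data frame holding the two label columns; pass the
#'   column names (unquoted behaviour is not needed — the defaults `truth`
#'   and `pred` are looked up by name). Alternatively leave `data = NULL`
#'   and supply `truth` and `pred` vectors directly.
#' @param truth,pred Comma-joined label strings (`""` = no modification) or
#'   lists of character vectors; either column names into `data` or bare
#'   vectors.
#' @param convention `"null"` (explicit null label, L = 6) or `"strict"`
#'   (L = 5, 0/0 := 1).
#' @return A one-row tibble: `aiming`, `coverage`, `accuracy`,
#'   `absolute_true`, `absolute_false` (all in `[0, 1]`), `n`, `l`.
#' @examples
#' multilabel_metrics(truth = c("acetylation", ""),
#'                    pred = c("acetylation,methylation", ""))
#' @export
multilabel_metrics <- function(data = NULL, truth = "truth", pred = "pred",
                               convention = c("null", "strict")) {
  convention <- match.arg(convention)
  if (!is.null(data)) {
    truth <- data[[truth]]
    pred <- data[[pred]]
  }
  ts <- as_label_sets(truth)
  ps <- as_label_sets(pred)
  if (length(ts) != length(ps)) {
    abort("`truth` and `pred` differ in length.", class = "kptm_shape_error")
  }
  universe <- kptm_labels()
  if (convention == "null") {
    nul <- kptm_null_label()
    ts <- lapply(ts, function(s) if (length(s) == 0) nul else s)
    ps <- lapply(ps, function(s) if (length(s) == 0) nul else s)
    universe <- c(universe, nul)
  }
  bad <- setdiff(unique(unlist(c(ts, ps))), universe)
  if (length(bad) > 0) {
    abort(paste0("Label(s) outside the universe: ", paste(bad, collapse = ", ")),
          class = "kptm_key_error")
  }
  n <- length(ts)
  l <- length(universe)
  inter <- mapply(function(a, b) length(intersect(a, b)), ts, ps)
  uni <- mapply(function(a, b) length(union(a, b)), ts, ps)
  ratio0 <- function(num, den) ifelse(den == 0, 1, num / ifelse(den == 0, 1, den))
  tibble(
    aiming = mean(ratio0(inter, lengths(ps))),
    coverage = mean(ratio0(inter, lengths(ts))),
    accuracy = mean(ratio0(inter, uni)),
    absolute_true = mean(uni == inter & lengths(ts) == lengths(ps)),
    absolute_false = mean((uni - inter) / l),
    n = n, l = l)
}

as_label_sets <- function(x) {
  if (is.list(x)) {
    lapply(x, function(s) unique(as.character(s[nzchar(s)])))
  } else {
    lapply(split_labels(x), function(s) unique(s[nzchar(s)]))
  }
}
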