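#' Different-error-cost (DEC) class weights
#'
#' Weights `w_pos = M / (2 * M1)` and `w_neg = M / (2 * M2)` (with
#' `M = M1 + M2` samples, `M1` positives, `M2` negatives) that rescale the
#' SVM misclassification cost per class, so the rarer class is the more
#' expensive one to misclassify. Balanced counts give both weights 1, and
#' `w_pos * M1 + w_neg * M2 == M` always.
#'
#' @param n_pos,n_neg Positive / negative training counts (both >= 1).
#' @return A one-row tibble with columns `w_pos`, `w_neg`, `m`, `m1`, `m2`.
#' @examples
#' dec_weights(20, 80)
#' @export
dec_weights <- function(n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) {
    abort("Both classes need at least one sample.",
          class = "kptm_degenerate_labels")
  }
  m <- n_pos + n_neg
  tibble(w_pos = m / (2 * n_pos), w_neg = m / (2 * n_neg),
         m = m, m1 = n_pos, m2 = n_neg)
}

#' Instance hardness via an out-of-fold cost-sensitive SVM
#'
#' The hardness of a sample is `1 - p(true label)`, where the probability
#' comes from a cost-sensitive RBF-SVM with Platt probability calibration
#' that never saw the sample: the data are split into stratified folds and
#' each fold is scored by a model trained on the remaining folds. High
#' hardness flags samples that are noisy or sit on the class border.
#'
#' @param features Data frame or matrix of numeric features — for the
#'   undersampling stage these are the sequence-coupling features of the
#'   primary dataset (see [balance_dataset()]).
#' @param labels Logical (or 0/1) vector: `TRUE` for the modified (K-PTM)
#'   class.
#' @param n_folds Out-of-fold split count (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble with columns `hardness` (in `[0, 1]`) and `fold`.
#' @export
instance_hardness <- function(features, labels, n_folds = 5L, seed = 0L) {
  x <- as.matrix(features)
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present to estimate hardness.",
          class = "kptm_degenerate_labels")
  }
  fold <- stratified_folds(y, n_folds, seed)
  hardness <- rep(NA_real_, length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- svm_binary(x[tr, , drop = FALSE], y[tr])
    # Platt calibration on the training fold's own decision scores: a
    # deterministic logistic map from score to p(positive).
    s_tr <- svm_scores(fit, x[tr, , drop = FALSE])$score
    calib <- suppressWarnings(
      stats::glm(y[tr] ~ s_tr, family = stats::binomial()))
    s_va <- svm_scores(fit, x[!tr, , drop = FALSE])$score
    p <- as.numeric(predict(calib, newdata = data.frame(s_tr = s_va),
                            type = "response"))
    truth <- y[!tr]
    hardness[!tr] <- 1 - ifelse(truth, p, 1 - p)
  }
  tibble(hardness = hardness, fold = fold)
}

# Stratified fold assignment: within each stratum, shuffle then deal
# round-robin starting from a rotating fold, so strata smaller than
# n_folds still spread across different folds.
stratified_folds <- function(strata, n_folds, seed) {
  fold <- integer(length(strata))
  withr::with_seed(seed, {
    start <- 0L
    for (s in unique(strata)) {
      i <- which(strata == s)
      i <- i[sample.int(length(i))]
      fold[i] <- ((start + seq_along(i) - 1L) %% n_folds) + 1L
      start <- (start + length(i)) %% n_folds
    }
  })
  fold
}

#' Undersample the unmodified majority class by instance hardness
#'
#' Removes the highest-hardness Non-K-PTM (empty-label) samples until the
#' majority:minority ratio reaches `ratio` (1:1 by default). Modified
#' samples are never removed, survivors keep their window strings and label
#' sets untouched, and ties in hardness are broken by original sample order
#' so runs are reproducible.
#'
#' @param data A `kptm_dataset`.
#' @param hardness Numeric vector aligned with `data` rows (e.g. the
#'   `hardness` column of [instance_hardness()]).
#' @param ratio Target majority-to-minority ratio (default 1).
#' @return The filtered `kptm_dataset`, rows in original order. If the
#'   target is not reachable (majority already at or below it) the dataset
#'   is returned unchanged with a warning.
#' @export
undersample_majority <- function(data, hardness, ratio = 1.0) {
  stopifnot(length(hardness) == nrow(data))
  is_neg <- data$labels == ""
  n_min <- sum(!is_neg)
  n_maj <- sum(is_neg)
  target <- as.integer(round(ratio * n_min))
  if (n_maj <= target) {
    warn(sprintf(
      "Majority class (%d) already at or below the target %d; nothing removed.",
      n_maj, target))
    return(data)
  }
  neg_idx <- which(is_neg)
  # ascending hardness, stable in original order; keep the easiest `target`
  keep_neg <- neg_idx[order(hardness[neg_idx])][seq_len(target)]
  keep <- sort(c(which(!is_neg), keep_neg))
  data[keep, , drop = FALSE]
}

#' Balance a benchmark dataset (hardness undersampling stage)
#'
#' The first of the two imbalance stages: fits the sequence-coupling model
#' on the modified vs unmodified windows of the primary dataset, scores
#' every sample's instance hardness on those coupling features with an
#' out-of-fold cost-sensitive SVM, and drops the hardest unmodified samples
#' down to the requested ratio. (The second stage, DEC class weights inside
#' each per-PTM classifier, happens at training time.)
#'
#' @inheritParams undersample_majority
#' @inheritParams instance_hardness
#' @param pseudocount Smoothing for [fit_coupling()].
#' @return The balanced `kptm_dataset`; the per-sample audit table
#'   (window, hardness, kept flag) is attached as `attr(, "hardness")`.
#' @export
balance_dataset <- function(data, ratio = 1.0, pseudocount = 1e-4,
                            n_folds = 5L, seed = 0L) {
  is_pos <- data$labels != ""
  model <- fit_coupling(data$window[is_pos], data$window[!is_pos],
                        pseudocount = pseudocount)
  feats <- encode_coupling(data$window, model)
  h <- instance_hardness(feats, is_pos, n_folds = n_folds, seed = seed)
  out <- undersample_majority(data, h$hardness, ratio = ratio)
  audit <- tibble(window = data$window, hardness = h$hardness,
                  kept = data$window %in% out$window)
  attr(out, "hardness") <- audit
  out
}
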