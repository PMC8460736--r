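#' SVM head configuration
#'
#' Defaults follow libSVM's: misclassification cost `C = 1` and RBF width
#' `gamma = 1/n_features` (resolved at fit time from the training matrix).
#' Class weights default to the DEC weights of the training split
#' ([dec_weights()]), so residual per-PTM imbalance is absorbed by
#' asymmetric costs `C * w_pos` and `C * w_neg`.
#'
#' @param cost Misclassification cost `C` (> 0).
#' @param gamma RBF kernel width; `NULL` means `1/n_features`.
#' @param class_weights `"dec"` (default), `"none"`, or a numeric
#'   `c(pos = , neg = )` pair.
#' @param probability Also fit Platt probability calibration.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = NULL, class_weights = "dec",
                       probability = FALSE) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma, class_weights = class_weights,
                 probability = probability),
            class = "svm_config")
}

# low-level fit: y logical, positive class TRUE
svm_binary <- function(x, y, cost = 1, gamma = NULL, weights = NULL,
                       probability = FALSE) {
  y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  if (is.null(weights)) {
    w <- dec_weights(sum(y == "pos"), sum(y == "neg"))
    weights <- c(neg = w$w_neg, pos = w$w_pos)
  }
  svm(x, y, type = "C-classification", kernel = "radial",
      cost = cost, gamma = gamma, class.weights = weights,
      probability = probability, scale = FALSE)
}

# decision scores oriented so score > 0 => positive class; optionally
# calibrated probabilities
svm_scores <- function(fit, x, probability = FALSE) {
  pr <- predict(fit, x, decision.values = TRUE,
                probability = probability && !is.null(fit$compprob) && fit$compprob)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv)
  if (colnames(dv)[1] == "neg/pos") score <- -score
  out <- tibble(score = score)
  probs <- attr(pr, "probabilities")
  if (!is.null(probs)) out$prob_pos <- probs[, "pos"]
  out
}

#' Train one cost-sensitive binary SVM head
#'
#' Fits an RBF-kernel support vector machine for a single PTM type, with
#' per-class costs `C * w_pos` / `C * w_neg`. When a training split has a
#' single class (possible for very rare PTM types in small folds) a
#' constant head is returned that scores every sample as the observed
#' class, with a warning.
#'
#' @param features Data frame or matrix of numeric training features.
#' @param labels Logical vector, `TRUE` for the positive class.
#' @param config An [svm_config()].
#' @param allow_constant Return a constant head instead of erroring on a
#'   single-class split.
#' @return A `kptm_head` exposing decision scores via [predict_scores()];
#'   records the feature-column contract.
#' @export
train_binary <- function(features, labels, config = svm_config(),
                         allow_constant = FALSE) {
  x <- as.matrix(features)
  y <- as.logical(labels)
  cols <- colnames(x)
  if (length(unique(y)) < 2L) {
    if (!allow_constant) {
      abort("Training data contains a single class.",
            class = "kptm_degenerate_labels")
    }
    warn("Single-class training split; using a constant head.")
    return(structure(list(constant = if (y[1]) 1 else -1, columns = cols),
                     class = "kptm_head"))
  }
  weights <- if (identical(config$class_weights, "dec")) {
    NULL # resolved from training counts inside svm_binary
  } else if (identical(config$class_weights, "none")) {
    c(neg = 1, pos = 1)
  } else {
    c(neg = unname(config$class_weights[["neg"]]),
      pos = unname(config$class_weights[["pos"]]))
  }
  fit <- svm_binary(x, y, cost = config$cost, gamma = config$gamma,
                    weights = weights, probability = config$probability)
  structure(list(fit = fit, columns = cols), class = "kptm_head")
}

#' Decision scores of a fitted binary head
#'
#' @param head A `kptm_head` from [train_binary()].
#' @param features Feature table whose columns match the head's training
#'   columns.
#' @param probability Also return calibrated probabilities (heads fitted
#'   with `probability = TRUE` only).
#' @return A tibble with column `score` (sign > 0 predicts the positive
#'   class) and optionally `prob_pos`.
#' @export
predict_scores <- function(head, features, probability = FALSE) {
  x <- as.matrix(features)
  if (!is.null(head$columns) && !is.null(colnames(x)) &&
      !identical(colnames(x), head$columns)) {
    abort("Feature columns do not match the head's training columns.",
          class = "kptm_shape_error")
  }
  if (!is.null(head$constant)) {
    return(tibble(score = rep(head$constant, nrow(x))))
  }
  svm_scores(head$fit, x, probability = probability)
}
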