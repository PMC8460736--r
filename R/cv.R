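#' Repeated stratified cross-validation of the multi-label predictor
#'
#' Runs `n_repeats` complete rounds of `n_folds`-fold cross-validation
#' (default 5 x 5). Folds are stratified by label-set combination so each
#' label's prevalence is preserved as far as its count allows. Within every
#' training fold the whole pipeline is refitted from scratch — coupling
#' model, standardisation, ANOVA ranking (in the default `"fold"` selection
#' mode), DEC weights and the five SVM heads — and the held-out fold is
#' scored with those frozen components, so no validation information
#' reaches any trained part. Chou's five metrics are computed on the pooled
#' out-of-fold predictions of each repeat.
#'
#' @param data A balanced `kptm_dataset`.
#' @param config A [pipeline_config()]; `n_folds`, `n_repeats`, `seeds`,
#'   `selection` and `convention` are taken from it.
#' @return A `kptm_cv` object: `per_repeat` metrics tibble (one row per
#'   repeat, with its seed), `summary` (mean and sd per metric),
#'   `predictions` (pooled out-of-fold predictions of the first repeat) and
#'   the protocol. Supports [tidy()], [glance()] and [autoplot()].
#' @export
cross_validate <- function(data, config = pipeline_config()) {
  if (nrow(data) < config$n_folds) {
    abort("Fewer samples than folds.", class = "kptm_empty_input")
  }
  windows <- data$window
  labmat <- label_matrix(data)
  static <- encode_static(windows, config)
  per_repeat <- list()
  first_preds <- NULL
  for (r in seq_len(config$n_repeats)) {
    seed <- config$seeds[r]
    fold <- stratified_folds(data$labels, config$n_folds, seed)
    pred <- rep(NA_character_, nrow(data))
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      fit <- fit_pipeline(windows[tr], labmat[tr, , drop = FALSE], config,
                          static = static[tr, , drop = FALSE],
                          allow_constant = TRUE)
      out <- predict_pipeline(fit, windows[!tr],
                              static = static[!tr, , drop = FALSE])
      pred[!tr] <- out$labels
    }
    mt <- multilabel_metrics(truth = data$labels, pred = pred,
                             convention = config$convention)
    per_repeat[[r]] <- dplyr::mutate(mt, repeat_id = r, seed = seed,
                                     .before = 1L)
    if (r == 1L) {
      first_preds <- tibble(window = windows, truth = data$labels,
                            pred = pred, fold = fold)
    }
  }
  per_repeat <- dplyr::bind_rows(per_repeat)
  metric_cols <- c("aiming", "coverage", "accuracy", "absolute_true",
                   "absolute_false")
  summary <- tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_repeat[[m]]), numeric(1)))
  structure(list(per_repeat = per_repeat, summary = summary,
                 predictions = first_preds,
                 protocol = list(n_folds = config$n_folds,
                                 n_repeats = config$n_repeats,
                                 seeds = config$seeds[seq_len(config$n_repeats)],
                                 selection = config$selection,
                                 convention = config$convention)),
            class = "kptm_cv")
}

#' @export
print.kptm_cv <- function(x, ...) {
  cat(sprintf("<kptm_cv> %d x %d-fold cross-validation (selection: %s)\n",
              x$protocol$n_repeats, x$protocol$n_folds, x$protocol$selection))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %6.2f%% +/- %.2f\n", s$metric[i], 100 * s$mean[i],
                100 * (if (is.na(s$sd[i])) 0 else s$sd[i])))
  }
  invisible(x)
}
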