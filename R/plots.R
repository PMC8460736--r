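#' Plot methods
#'
#' `autoplot()` for the package's result objects: the IFS curves
#' (multi-label accuracy and absolute-false against the number of leading
#' features), the cross-validation metric summary (mean with +/- 1 sd
#' bars), and the label-multiplicity histogram of a benchmark dataset.
#'
#' @param object A `kptm_ifs`, `kptm_cv` or `kptm_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name kptm-autoplot
NULL

#' @rdname kptm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.kptm_ifs <- function(object, ...) {
  long <- tidyr::pivot_longer(object$grid, c("accuracy", "absolute_false"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_m, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "leading features (m)", y = NULL,
                  title = "Incremental feature selection",
                  subtitle = sprintf("best m = %d", object$best_m)) +
    ggplot2::theme_minimal()
}

#' @rdname kptm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.kptm_cv <- function(object, ...) {
  s <- object$summary
  s$metric <- factor(s$metric, levels = s$metric)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d x %d-fold cross-validation",
                                  object$protocol$n_repeats,
                                  object$protocol$n_folds)) +
    ggplot2::theme_minimal()
}

#' @rdname kptm-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.kptm_dataset <- function(object, ...) {
  h <- label_multiplicity(object)
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$n_labels),
                                  y = .data$n_samples)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "labels per sample (0 = Non-K-PTM)", y = "samples",
                  title = "Label multiplicity") +
    ggplot2::theme_minimal()
}
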