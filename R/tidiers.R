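#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per-repeat metrics for `kptm_cv`, the IFS grid for `kptm_ifs`, the
#' per-PTM selected features for `kptm_model`), `glance()` a one-row
#' summary.
#'
#' @param x A `kptm_cv`, `kptm_ifs` or `kptm_model` object.
#' @param ... Unused.
#' @return A tibble.
#' @name kptm-tidiers
NULL

#' @rdname kptm-tidiers
#' @exportS3Method generics::tidy
tidy.kptm_cv <- function(x, ...) {
  x$per_repeat
}

#' @rdname kptm-tidiers
#' @exportS3Method generics::glance
glance.kptm_cv <- function(x, ...) {
  s <- x$summary
  out <- c(stats::setNames(as.list(s$mean), s$metric),
           stats::setNames(as.list(s$sd), paste0(s$metric, "_sd")))
  tibble(!!!out, n_folds = x$protocol$n_folds,
         n_repeats = x$protocol$n_repeats)
}

#' @rdname kptm-tidiers
#' @exportS3Method generics::tidy
tidy.kptm_ifs <- function(x, ...) {
  x$grid
}

#' @rdname kptm-tidiers
#' @exportS3Method generics::glance
glance.kptm_ifs <- function(x, ...) {
  best <- x$grid[x$grid$m == x$best_m, ][1, ]
  tibble(best_m = x$best_m, accuracy = best$accuracy,
         absolute_false = best$absolute_false, n_grid = nrow(x$grid),
         selection = x$selection)
}

#' @rdname kptm-tidiers
#' @exportS3Method generics::tidy
tidy.kptm_model <- function(x, ...) {
  purrr::imap_dfr(x$selected, ~tibble(ptm = .y, rank = seq_along(.x),
                                      feature = .x))
}

#' @rdname kptm-tidiers
#' @exportS3Method generics::glance
glance.kptm_model <- function(x, ...) {
  sel <- tidy(x)
  enc <- sub(":.*$", "", sel$feature)
  tibble(n_features = nrow(x$scaler),
         top_m = if (is.null(x$config$top_m)) nrow(x$scaler) else x$config$top_m,
         zeta = x$zeta %||% x$config$zeta,
         coupling_share = mean(enc == "coupling"))
}
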