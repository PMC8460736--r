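#' Full pipeline configuration
#'
#' Collects every tunable of the prediction pipeline. The defaults are the
#' package's reference operating point: half-window `zeta = 24` (49-residue
#' windows), all four encoders with CKSAAP spacings `k = 0..4` (3527
#' ensemble columns), coupling pseudocount `1e-4`, 1:1 hardness
#' undersampling, `top_m = 100` ANOVA-selected features per PTM task,
#' libSVM-default SVM heads (`C = 1`, `gamma = 1/n_features`) with DEC
#' class weights, 5x5-fold cross-validation, and the null-label metrics
#' convention.
#'
#' @param zeta Half-window size.
#' @param encoders Encoder subset (see [encode_ensemble()]).
#' @param k_values CKSAAP spacings.
#' @param pseudocount Coupling smoothing.
#' @param ratio Undersampling majority:minority target.
#' @param top_m Features kept per PTM task after ANOVA ranking; `NULL`
#'   keeps all.
#' @param selection `"fold"` re-ranks inside each training fold (the
#'   leakage-safe default for cross-validation); `"global"` ranks once on
#'   the full data, as benchmark replications usually do.
#' @param grid_step IFS grid spacing.
#' @param svm An [svm_config()].
#' @param n_folds,n_repeats,seeds Cross-validation protocol (seeds default
#'   to `0:(n_repeats - 1)`).
#' @param convention Metrics label convention.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(zeta = 24L,
                            encoders = c("aaf", "binary", "cksaap", "coupling"),
                            k_values = 0:4, pseudocount = 1e-4, ratio = 1.0,
                            top_m = 100L, selection = c("fold", "global"),
                            grid_step = 50L, svm = svm_config(),
                            n_folds = 5L, n_repeats = 5L, seeds = NULL,
                            convention = c("null", "strict")) {
  structure(list(zeta = as.integer(zeta), encoders = encoders,
                 k_values = as.integer(k_values), pseudocount = pseudocount,
                 ratio = ratio, top_m = top_m,
                 selection = match.arg(selection),
                 grid_step = as.integer(grid_step), svm = svm,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seeds = seeds %||% (seq_len(n_repeats) - 1L),
                 convention = match.arg(convention)),
            class = "pipeline_config")
}

# The non-coupling encoder blocks depend only on the window strings, so
# they can be computed once and reused across folds without leakage.
encode_static <- function(windows, config) {
  enc <- setdiff(config$encoders, "coupling")
  if (length(enc) == 0) return(NULL)
  as.matrix(encode_ensemble(windows, encoders = enc,
                            k_values = config$k_values))
}

# Fit every trained component on (windows, label matrix): coupling model,
# scaler, per-PTM rankings/selections, DEC-weighted SVM heads.
fit_pipeline <- function(windows, labmat, config, static = NULL,
                         allow_constant = FALSE) {
  is_pos <- rowSums(labmat) > 0
  feats <- static %||% encode_static(windows, config)
  coupling <- NULL
  if ("coupling" %in% config$encoders) {
    if (!any(is_pos) || all(is_pos)) {
      abort("Coupling fit needs both modified and unmodified windows.",
            class = "kptm_empty_input")
    }
    coupling <- fit_coupling(windows[is_pos], windows[!is_pos],
                             pseudocount = config$pseudocount)
    feats <- cbind(feats, as.matrix(encode_coupling(windows, coupling)))
  }
  scaler <- suppressWarnings(fit_scaler(feats))
  feats <- as.matrix(apply_scaler(as_tibble(feats), scaler))
  heads <- list()
  selected <- list()
  for (ptm in kptm_labels()) {
    y <- labmat[, ptm]
    cols <- colnames(feats)
    if (!is.null(config$top_m) && config$top_m < ncol(feats)) {
      cols <- if (length(unique(y)) < 2L) {
        # no positives for this task in the split: ranking is undefined and
        # the head is constant; keep the leading columns for the contract
        cols[seq_len(config$top_m)]
      } else {
        rank_features(feats, y)$feature[seq_len(config$top_m)]
      }
    }
    heads[[ptm]] <- train_binary(feats[, cols, drop = FALSE], y, config$svm,
                                 allow_constant = allow_constant)
    selected[[ptm]] <- cols
  }
  structure(list(coupling = coupling, scaler = scaler, heads = heads,
                 selected = selected, config = config),
            class = "kptm_model")
}

predict_pipeline <- function(model, windows, static = NULL) {
  config <- model$config
  feats <- static %||% encode_static(windows, config)
  if (!is.null(model$coupling)) {
    feats <- cbind(feats, as.matrix(encode_coupling(windows, model$coupling)))
  }
  feats <- as.matrix(apply_scaler(as_tibble(feats), model$scaler))
  scores <- vapply(kptm_labels(), function(ptm) {
    predict_scores(model$heads[[ptm]],
                   feats[, model$selected[[ptm]], drop = FALSE])$score
  }, numeric(length(windows)))
  scores <- matrix(scores, nrow = length(windows),
                   dimnames = list(NULL, kptm_labels()))
  pred <- apply(scores > 0, 1L, function(z) join_labels(kptm_labels()[z]))
  list(scores = scores, labels = pred)
}

#' Train the five-head multi-label K-PTM predictor
#'
#' Fits the whole pipeline on a (typically balanced) benchmark dataset:
#' sequence-coupling model on modified vs unmodified windows, feature
#' ensemble with z-score standardisation, per-PTM ANOVA top-`m` selection,
#' and one cost-sensitive RBF-SVM head per PTM type with DEC class weights
#' from that task's training counts. Each label is assigned independently
#' by its head (decision score > 0); an empty predicted set means
#' Non-K-PTM.
#'
#' @param data A `kptm_dataset` (see [build_benchmark()],
#'   [balance_dataset()]).
#' @param config A [pipeline_config()].
#' @return A `kptm_model`; use [predict()][predict.kptm_model] on new
#'   proteins or windows, [save_model()] to persist.
#' @export
train_multilabel <- function(data, config = pipeline_config()) {
  if (nrow(data) == 0) abort("Empty dataset.", class = "kptm_empty_input")
  fit <- fit_pipeline(data$window, label_matrix(data), config,
                      allow_constant = TRUE)
  fit$zeta <- attr(data, "zeta") %||% config$zeta
  fit
}

#' Predict K-PTM label sets for proteins or peptide windows
#'
#' When given a protein table (columns `id`, `sequence`), every lysine is
#' scored; when given a dataset or window vector, rows are scored as-is.
#'
#' @param object A `kptm_model`.
#' @param new_data Tibble of proteins (`id`, `sequence`), a `kptm_dataset`,
#'   or a character vector of windows.
#' @param ... Unused.
#' @return A tibble with `protein_id`, `position` (where applicable),
#'   `window`, `predicted_labels` (comma-joined, `""` for Non-K-PTM) and
#'   one `score_<ptm>` column per PTM type.
#' @export
predict.kptm_model <- function(object, new_data, ...) {
  if (is.data.frame(new_data) && all(c("id", "sequence") %in% names(new_data))) {
    ds <- build_benchmark(new_data, NULL, zeta = object$zeta)
    meta <- ds[c("protein_id", "position", "window")]
  } else {
    windows <- as_windows(new_data)
    meta <- tibble(window = windows)
    if (is.data.frame(new_data) &&
        all(c("protein_id", "position") %in% names(new_data))) {
      meta <- tibble(protein_id = new_data$protein_id,
                     position = new_data$position, window = windows)
    }
  }
  if (nrow(meta) == 0) {
    return(dplyr::bind_cols(meta, tibble(predicted_labels = character(0)),
                            as_tibble(matrix(numeric(0), 0, 5,
                              dimnames = list(NULL, paste0("score_", kptm_labels()))))))
  }
  res <- predict_pipeline(object, meta$window)
  scores <- as_tibble(res$scores)
  names(scores) <- paste0("score_", names(scores))
  dplyr::bind_cols(meta, tibble(predicted_labels = res$labels), scores)
}

#' @export
print.kptm_model <- function(x, ...) {
  cat(sprintf(
    "<kptm_model> 5 SVM heads, zeta = %d, top_m = %s, %d scaled features\n",
    x$zeta %||% x$config$zeta,
    if (is.null(x$config$top_m)) "all" else x$config$top_m,
    nrow(x$scaler)))
  invisible(x)
}

#' Save / load a trained predictor bundle
#'
#' Writes the model to a directory: coupling model as JSON, scaler and
#' per-PTM selected columns as TSV, a JSON config manifest, and the five
#' fitted heads as RDS files.
#'
#' @param model A `kptm_model`.
#' @param dir Bundle directory (created if missing).
#' @return `dir` (`save_model`) or a `kptm_model` (`load_model`).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(model$coupling)) {
    write_coupling(model$coupling, file.path(dir, "coupling.json"))
  }
  readr::write_tsv(model$scaler, file.path(dir, "scaler.tsv"))
  sel <- purrr::imap_dfr(model$selected, ~tibble(ptm = .y, feature = .x))
  readr::write_tsv(sel, file.path(dir, "selected.tsv"))
  jsonlite::write_json(
    list(zeta = model$zeta, config = unclass(model$config)[
      c("zeta", "encoders", "k_values", "pseudocount", "top_m", "convention")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  for (ptm in names(model$heads)) {
    saveRDS(model$heads[[ptm]], file.path(dir, paste0("head_", ptm, ".rds")))
  }
  saveRDS(model$config, file.path(dir, "config.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  config <- readRDS(file.path(dir, "config.rds"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  coupling <- if (file.exists(file.path(dir, "coupling.json"))) {
    read_coupling(file.path(dir, "coupling.json"))
  }
  sel <- readr::read_tsv(file.path(dir, "selected.tsv"), show_col_types = FALSE)
  heads <- stats::setNames(lapply(kptm_labels(), function(ptm)
    readRDS(file.path(dir, paste0("head_", ptm, ".rds")))), kptm_labels())
  structure(list(coupling = coupling,
                 scaler = readr::read_tsv(file.path(dir, "scaler.tsv"),
                                          show_col_types = FALSE),
                 heads = heads,
                 selected = split(sel$feature, sel$ptm)[kptm_labels()],
                 config = config, zeta = as.integer(manifest$zeta)),
            class = "kptm_model")
}
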