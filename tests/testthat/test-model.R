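test_that("balanced training sets give equal per-class costs", {
  w <- dec_weights(50, 50)
  expect_equal(w$w_pos, w$w_neg)
  blobs <- toy_blobs(n_per = 25, sep = 6)
  head_fit <- train_binary(blobs$x, blobs$y)
  pred <- predict_scores(head_fit, blobs$x)
  expect_equal(pred$score > 0, blobs$y) # separable floor
})

test_that("swapping class roles flips the sign of decision scores", {
  blobs <- toy_blobs(n_per = 25, sep = 4)
  f1 <- train_binary(blobs$x, blobs$y)
  f2 <- train_binary(blobs$x, !blobs$y)
  s1 <- predict_scores(f1, blobs$x)$score
  s2 <- predict_scores(f2, blobs$x)$score
  expect_equal(s1, -s2, tolerance = 1e-8)
})

test_that("single-class training errors unless a constant head is allowed", {
  blobs <- toy_blobs(n_per = 10)
  expect_error(train_binary(blobs$x, rep(TRUE, 20)),
               class = "kptm_degenerate_labels")
  expect_warning(
    h <- train_binary(blobs$x, rep(FALSE, 20), allow_constant = TRUE),
    "constant head")
  expect_true(all(predict_scores(h, blobs$x)$score < 0))
})

test_that("heads combine independently into multi-label predictions", {
  b <- small_benchmark()
  bal <- suppressWarnings(balance_dataset(b$dataset, seed = 0))
  cfg <- pipeline_config(zeta = 6, top_m = 60, n_repeats = 1)
  model <- suppressWarnings(train_multilabel(bal, cfg))
  pred <- predict(model, bal)
  expect_equal(nrow(pred), nrow(bal))
  scores <- as.matrix(pred[paste0("score_", kptm_labels())])
  # label predicted iff its head's decision score crosses zero
  for (i in seq_along(kptm_labels())) {
    in_set <- vapply(kptm:::split_labels(pred$predicted_labels),
                     function(s) kptm_labels()[i] %in% s, logical(1))
    expect_equal(in_set, unname(scores[, i] > 0))
  }
  # all-negative scores mean the empty (Non-K-PTM) set
  allneg <- rowSums(scores > 0) == 0
  expect_true(all(pred$predicted_labels[allneg] == ""))
})

test_that("prediction on proteins without lysines returns an empty table", {
  b <- small_benchmark()
  bal <- suppressWarnings(balance_dataset(b$dataset, seed = 0))
  model <- suppressWarnings(
    train_multilabel(bal, pipeline_config(zeta = 6, top_m = 40)))
  noK <- tibble::tibble(id = "P0", sequence = "AAAGGGCCC")
  pred <- predict(model, noK)
  expect_equal(nrow(pred), 0)
  expect_true(all(c("predicted_labels", "score_acetylation") %in% names(pred)))
})

test_that("model bundles round-trip through disk", {
  b <- small_benchmark()
  bal <- suppressWarnings(balance_dataset(b$dataset, seed = 0))
  model <- suppressWarnings(
    train_multilabel(bal, pipeline_config(zeta = 6, top_m = 40)))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  p1 <- predict(model, bal[1:10, ])
  p2 <- predict(back, bal[1:10, ])
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("cross-validation is reproducible and reports one row per repeat", {
  b <- small_benchmark()
  bal <- suppressWarnings(balance_dataset(b$dataset, seed = 0))
  cfg <- pipeline_config(zeta = 6, top_m = 40, n_folds = 3, n_repeats = 2,
                         seeds = c(4, 9))
  cv1 <- suppressWarnings(cross_validate(bal, cfg))
  cv2 <- suppressWarnings(cross_validate(bal, cfg))
  expect_identical(tidy(cv1), tidy(cv2))
  expect_equal(nrow(tidy(cv1)), 2)
  expect_equal(tidy(cv1)$seed, c(4, 9))
  g <- glance(cv1)
  expect_true(all(c("aiming", "coverage", "accuracy", "absolute_true",
                    "absolute_false") %in% names(g)))
})

test_that("no validation information reaches trained components (canary)", {
  b <- small_benchmark()
  bal <- suppressWarnings(balance_dataset(b$dataset, seed = 0))
  cfg <- pipeline_config(zeta = 6, top_m = 40, n_folds = 3, n_repeats = 1)
  fold <- kptm:::stratified_folds(bal$labels, 3, cfg$seeds[1])
  tr <- fold != 1
  labmat <- label_matrix(bal)
  fit_clean <- kptm:::fit_pipeline(bal$window[tr], labmat[tr, ], cfg,
                                   allow_constant = TRUE)
  # corrupt every validation label; the trained fold model must not move
  corrupt <- bal
  withr::with_seed(99, {
    corrupt$labels[!tr] <- sample(c("", "crotonylation"), sum(!tr),
                                  replace = TRUE)
  })
  labmat2 <- label_matrix(corrupt)
  fit_dirty <- kptm:::fit_pipeline(corrupt$window[tr], labmat2[tr, ], cfg,
                                   allow_constant = TRUE)
  p1 <- kptm:::predict_pipeline(fit_clean, bal$window[!tr])
  p2 <- kptm:::predict_pipeline(fit_dirty, bal$window[!tr])
  expect_identical(p1$scores, p2$scores)
  expect_identical(fit_clean$scaler, fit_dirty$scaler)
  expect_identical(fit_clean$selected, fit_dirty$selected)
})

test_that("calibrated probability 0.5 and decision score 0 agree on the toy fixture", {
  blobs <- toy_blobs(n_per = 30, sep = 4)
  head_fit <- train_binary(blobs$x, blobs$y,
                           svm_config(probability = TRUE))
  pred <- predict_scores(head_fit, blobs$x, probability = TRUE)
  expect_true(all((pred$score > 0) == (pred$prob_pos > 0.5)))
})
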