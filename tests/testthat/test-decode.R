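test_that("model configuration encodes the per-decoder hyperparameters", {
  c1 <- cnn_config("cnn1"); c2 <- cnn_config("cnn2b"); c3 <- cnn_config("cnn3")
  expect_equal(c(c1$epochs, c1$batch_size), c(100L, 128L))
  expect_equal(c(c2$epochs, c2$batch_size), c(150L, 128L))
  expect_equal(c(c3$epochs, c3$batch_size), c(100L, 32L))
  expect_equal(c1$conv_units, c(64L, 128L, 64L))
  expect_equal(c1$kernel_size, 3L)
})

test_that("built model has the printed architecture and sigmoid output", {
  cfg <- cnn_config("cnn2b", seed = 3)
  w <- build_cnn(4, cfg)
  expect_equal(nrow(w$W1), 64)
  expect_equal(nrow(w$W2), 128)
  expect_equal(nrow(w$W3), 64)
  expect_equal(ncol(w$W1), 4 * 3)    # kernel 3 over 4 input rows
  expect_equal(ncol(w$W2), 64 * 3)
  expect_equal(ncol(w$W3), 128 * 3)
  ds <- make_toy_dataset(n = 8)
  m <- structure(list(weights = w, config = cfg, input_shape = c(4L, 75L)),
                 class = "memburst_cnn")
  p <- predict_cnn(m, ds)
  expect_true(all(p > 0 & p < 1))
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- make_toy_dataset(n = 20, shift = 0.3)
  cfg <- cnn_config("cnn2b", epochs = 3, seed = 11)
  m1 <- train_cnn(ds, cfg)
  m2 <- train_cnn(ds, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict_cnn(m1, ds), predict_cnn(m2, ds))
})

test_that("cross-validation covers every trial exactly once, stratified", {
  ds <- make_toy_dataset(n = 40, shift = 0.5)
  cv <- crossvalidate(ds, cnn_config("cnn2b", epochs = 5, seed = 1),
                      k = 5, seed = 2)
  expect_equal(sort(cv$trial_id), 1:40)
  expect_false(anyNA(cv$probability))
  expect_equal(sort(unique(cv$fold)), 1:5)
  for (f in 1:5)  # both classes in every held-out fold
    expect_equal(sort(unique(cv$label[cv$fold == f])), c(0L, 1L))
  # a clearly separable shift is decoded well above chance
  expect_gt(auroc(cv$probability, cv$label), 0.85)
})

test_that("single-class datasets are rejected for training", {
  ds <- make_toy_dataset(n = 12)
  ds$labels <- rep(0L, 12)
  expect_error(train_cnn(ds, cnn_config("cnn2b", epochs = 2)), "class")
  expect_error(crossvalidate(ds, cnn_config("cnn2b", epochs = 2)), "class")
})

test_that("distinct train/test scoring is label-symmetric and overfit-ordered", {
  tr <- make_toy_dataset(n = 36, shift = 0.5, seed = 5)
  te <- make_toy_dataset(n = 36, shift = 0.5, seed = 6)
  cfg <- cnn_config("cnn2b", epochs = 15, seed = 4)
  pr <- train_test_distinct(tr, te, cfg)
  a <- auroc(pr$probability, pr$label)
  expect_gt(a, 0.7)  # transfers across independent draws of the same regime
  # inverted test labels mirror the AUROC
  te_flip <- te; te_flip$labels <- 1L - te$labels
  pr_flip <- train_test_distinct(tr, te_flip, cfg)
  expect_equal(auroc(pr_flip$probability, pr_flip$label), 1 - a,
               tolerance = 1e-12)
  # train = test is at least as good as generalization
  pr_self <- train_test_distinct(tr, tr, cfg)
  expect_gte(auroc(pr_self$probability, pr_self$label) + 1e-9, a - 0.05)
  # shape mismatch
  te_bad <- te; te_bad$tensors <- te$tensors[, 1:50, , drop = FALSE]
  expect_error(train_test_distinct(tr, te_bad, cfg), "shape")
})

test_that("evaluation summarizes pooled predictions coherently", {
  preds <- data.frame(trial_id = 1:6, fold = 1,
                      label = c(1, 1, 1, 0, 0, 0),
                      probability = c(.9, .8, .7, .3, .2, .1))
  res <- evaluate_predictions(preds)
  expect_equal(res$auroc, 1)
  expect_equal(res$youden$J, 1)
  expect_equal(res$youden$accuracy, 1)
  expect_equal(res$n, 6)
})

test_that("an identical row shuffle of every tensor leaves decoding intact", {
  ds <- make_toy_dataset(n = 40, n_rows = 4, shift = 0.5, seed = 9)
  perm <- c(3L, 1L, 4L, 2L)
  ds2 <- ds
  ds2$tensors <- ds$tensors[perm, , , drop = FALSE]
  cfg <- cnn_config("cnn2b", epochs = 10, seed = 2)
  auroc_from <- function(cv) auroc(cv$probability, cv$label)
  cv1 <- crossvalidate(ds, cfg, k = 5, seed = 3)
  cv2 <- crossvalidate(ds2, cfg, k = 5, seed = 3)
  expect_lt(abs(auroc_from(cv1) - auroc_from(cv2)), 0.15)
  expect_gt(auroc_from(cv2), 0.8)  # the class signal survives the shuffle
})

test_that("grouped folds fall back with a warning when lists are too few", {
  ds <- make_toy_dataset(n = 20, shift = 0.5, seed = 4)
  ds$group <- rep(1:3, length.out = 20)  # 3 lists, k = 5
  expect_warning(cv <- crossvalidate(ds, cnn_config("cnn2b", epochs = 2),
                                     k = 5, seed = 1),
                 "fewer lists")
  expect_false(anyNA(cv$probability))
})
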