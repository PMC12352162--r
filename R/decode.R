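subset_dataset <- function(dataset, idx) {
  new_labeled_dataset(dataset$tensors[, , idx, drop = FALSE],
                      dataset$labels[idx], dataset$trial_id[idx],
                      dataset$kind, dataset$fs_hz,
                      group = dataset$group[idx])
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin to folds, so every fold holds both classes whenever each
# class has >= k members
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# group-aware fold assignment: whole groups (lists) are dealt to folds so
# that trials cut from overlapping signal never span a train/test split;
# reshuffles until every fold's test and train sides hold both classes
grouped_folds <- function(labels, groups, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ug <- unique(groups)
  if (length(ug) < k)
    stop("need at least k = ", k, " groups (lists) for grouped folds")
  for (try in 1:50) {
    gf <- setNames(rep_len(seq_len(k), length(ug)), sample(ug))
    fold <- unname(gf[as.character(groups)])
    # every training side needs both classes; pooled scoring tolerates a
    # single-class test fold
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == 2, TRUE))
    if (ok) return(fold)
  }
  stop("could not build grouped folds with both classes on each side; ",
       "too few labeled examples per class")
}

#' Cross-validate a CNN decoder
#'
#' Stratified k-fold cross-validation (default 5-fold; use `k = n` for
#' leave-one-out): the model is retrained from scratch in every fold and
#' the test-fold probabilities are pooled into one set of out-of-fold
#' predictions, from which a single ROC per experiment is computed.
#'
#' Trials cut from the same list share overlapping signal (adjacent
#' encoding epochs overlap by up to half a second, random recall segments
#' by much more), so fold assignment is by list: all of a list's trials
#' land in one fold and no tensor content crosses a train/test boundary.
#' Trial-level stratified folds (used when the dataset carries no group
#' structure) would let the network recognize memorized content instead of
#' class structure.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @param config A [cnn_config()].
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold split and per-fold
#'   training (fold f trains with seed `seed + f`).
#' @return A `fold_predictions` data frame: trial_id, fold, label,
#'   probability.
#' @export
crossvalidate <- function(dataset, config = cnn_config(), k = 5L,
                          seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- n_trials(dataset)
  if (length(unique(dataset$labels)) < 2)
    stop("cross-validation requires both classes present")
  if (min(table(dataset$labels)) < k)
    stop("each class needs at least k = ", k, " members for stratified folds")
  grouped <- !is.null(dataset$group) &&
    length(unique(dataset$group)) < n  # real group structure present
  if (grouped && length(unique(dataset$group)) < k) {
    warning("fewer lists (", length(unique(dataset$group)),
            ") than folds (", k, "); falling back to trial-level folds, ",
            "which may leak overlapping epochs between train and test")
    grouped <- FALSE
  }
  fold <- if (grouped) grouped_folds(dataset$labels, dataset$group, k, seed)
  else stratified_folds(dataset$labels, k, seed)
  out <- data.frame(trial_id = dataset$trial_id, fold = fold,
                    label = dataset$labels, probability = NA_real_)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_cnn(subset_dataset(dataset, tr), cfg)
    out$probability[te] <- predict_cnn(model, subset_dataset(dataset, te))
  }
  class(out) <- c("fold_predictions", "data.frame")
  out
}

#' Train on one experiment, test on a distinct one
#'
#' A single model is trained on all of `train` and scored on all of
#' `test` (e.g. free-recall vs. categorical free-recall experiments of the
#' same subject), quantifying how much cross-validated scores are inflated
#' by overfitting.
#'
#' @param train,test `labeled_dataset`s with matching tensor shapes.
#' @param config A [cnn_config()].
#' @return A `fold_predictions` data frame (single fold 1).
#' @export
train_test_distinct <- function(train, test, config = cnn_config()) {
  if (!all(dim(train$tensors)[1:2] == dim(test$tensors)[1:2]))
    stop("train and test tensor shapes differ")
  model <- train_cnn(train, config)
  out <- data.frame(trial_id = test$trial_id, fold = 1L,
                    label = test$labels,
                    probability = predict_cnn(model, test))
  class(out) <- c("fold_predictions", "data.frame")
  out
}

#' Evaluate pooled fold predictions
#'
#' @param preds A `fold_predictions` data frame.
#' @return A `decode_result`: list with `auroc`, `roc` (curve), `youden`
#'   (confusion metrics at max J), `n`, and the predictions.
#' @export
evaluate_predictions <- function(preds) {
  stopifnot(all(c("label", "probability") %in% names(preds)))
  structure(list(auroc = auroc(preds$probability, preds$label),
                 roc = roc_curve(preds$probability, preds$label),
                 youden = youden_point(preds$probability, preds$label),
                 n = nrow(preds), predictions = preds),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Decode result: n = %d, AUROC = %.3f, Youden J = %.3f (sens %.3f, spec %.3f, acc %.3f)\n",
              x$n, x$auroc, x$youden$J, x$youden$sensitivity,
              x$youden$specificity, x$youden$accuracy))
  invisible(x)
}

#' Write fold predictions as TSV
#' @param preds A `fold_predictions` data frame.
#' @param path Output path.
#' @export
write_predictions_tsv <- function(preds, path) write_tsv(preds, path)
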