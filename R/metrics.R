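#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula, so ties contribute one
#' half: AUROC = P(score+ > score-) + 0.5 P(score+ = score-).
#'
#' @param probabilities Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return Scalar in \[0, 1\].
#' @export
auroc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probabilities) == length(labels),
            all(labels %in% 0:1))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(probabilities)  # midranks handle ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Thresholds are the unique scores in descending order (plus +Inf);
#' a case is called positive when its score is >= the threshold.
#'
#' @inheritParams auroc
#' @return A `roc_curve` data frame: threshold, sensitivity, fpr
#'   (1 - specificity), from (0, 0) to (1, 1).
#' @export
roc_curve <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC undefined: both classes must be present")
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(probabilities >= t & labels == 1), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(probabilities >= t & labels == 0), 0) / n_neg
  out <- data.frame(threshold = thr, sensitivity = sens, fpr = fpr)
  class(out) <- c("roc_curve", "data.frame")
  out
}

confusion_at <- function(probabilities, labels, threshold) {
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  # PPV and F1 are reported as 0 when no positive predictions are made
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  list(threshold = threshold, sensitivity = sens, specificity = spec,
       PPV = ppv, NPV = npv,
       accuracy = (tp + tn) / length(labels), F1 = f1,
       J = sens + spec - 1, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Confusion metrics at the maximum of Youden's J
#'
#' Scans every ROC threshold, computes J = sensitivity + specificity - 1,
#' and returns the full confusion metrics at the maximizing threshold.
#' Ties in J are broken toward higher sensitivity.
#'
#' @inheritParams auroc
#' @return A `confusion_metrics` list: threshold, sensitivity,
#'   specificity, PPV, NPV, accuracy, F1, J, and the raw counts.
#' @export
youden_point <- function(probabilities, labels) {
  labels <- as.integer(labels)
  curve <- roc_curve(probabilities, labels)
  metrics <- lapply(curve$threshold, confusion_at,
                    probabilities = probabilities, labels = labels)
  J <- vapply(metrics, `[[`, 0, "J")
  sens <- vapply(metrics, `[[`, 0, "sensitivity")
  best <- which(J >= max(J) - 1e-12)  # float-tolerant tie set
  best <- best[which.max(sens[best])]
  structure(metrics[[best]], class = "confusion_metrics")
}

#' Compare two sets of AUROC values with a t-test
#'
#' Two-sided paired or unpaired t-test, as used to compare decoder
#' variants (burst vs. broadband tensors) or recording regions.
#'
#' @param a,b Numeric vectors of AUROC (or accuracy) values.
#' @param paired Logical; paired requires equal lengths.
#' @return The `htest` object from [stats::t.test()].  For identical
#'   paired lists (zero variance of differences) t is reported as 0 and p
#'   as 1.
#' @export
compare_aurocs <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths")
  if (paired && stats::sd(a - b) == 0) {
    out <- list(statistic = c(t = 0), p.value = 1,
                estimate = c(`mean difference` = mean(a - b)),
                method = "Paired t-test (degenerate: zero variance)",
                alternative = "two.sided")
    class(out) <- "htest"
    return(out)
  }
  stats::t.test(a, b, paired = paired)
}
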