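#' Tile a tensor into (row, segment) cells
#'
#' Every row (electrode x band trace) is split into `n_segments` equal,
#' non-overlapping time segments that tile the row; remainders go to the
#' last segment.
#'
#' @param n_rows,n_samples Tensor dimensions.
#' @param n_segments Segments per row (default 10).
#' @return A `lime_segmentation`: list with `n_rows`, `n_segments`, and
#'   `breaks` (segment start/end sample per segment index).
#' @export
lime_segmentation <- function(n_rows, n_samples, n_segments = 10L) {
  stopifnot(n_rows >= 1, n_samples >= n_segments, n_segments >= 1)
  edges <- floor(seq(0, n_samples, length.out = n_segments + 1))
  breaks <- data.frame(segment = seq_len(n_segments),
                       start = edges[-length(edges)] + 1L,
                       end = edges[-1])
  structure(list(n_rows = as.integer(n_rows),
                 n_segments = as.integer(n_segments), breaks = breaks,
                 n_samples = as.integer(n_samples)),
            class = "lime_segmentation")
}

#' Generate perturbed copies of a tensor
#'
#' Each copy zeroes an independent random subset of (row, segment) cells
#' (each cell perturbed with probability `p_perturb`), leaving the rest
#' unchanged; zero is the natural "no burst" baseline of the non-negative
#' convolved series.  The binary mask records the perturbed cells
#' (1 = perturbed).
#'
#' @param tensor Rows x samples matrix.
#' @param segmentation A [lime_segmentation()].
#' @param n_samples Number of perturbed copies; must be at least twice the
#'   total cell count so the linear surrogate is identifiable.
#' @param seed Optional integer seed.
#' @param p_perturb Per-cell perturbation probability (default 0.5).
#' @return List: `masks` (n_samples x n_cells binary matrix, cells in
#'   row-major (row, segment) order) and `perturb` (function mapping a
#'   mask to the perturbed tensor).
#' @export
lime_perturb <- function(tensor, segmentation, n_samples, seed = NULL,
                         p_perturb = 0.5) {
  stopifnot(inherits(segmentation, "lime_segmentation"),
            nrow(tensor) == segmentation$n_rows)
  n_cells <- segmentation$n_rows * segmentation$n_segments
  if (n_samples < 2 * n_cells)
    stop("n_samples must be >= 2 x total segments (", 2 * n_cells, ")")
  if (!is.null(seed)) set.seed(seed)
  masks <- matrix(rbinom(n_samples * n_cells, 1, p_perturb), n_samples,
                  n_cells)
  br <- segmentation$breaks
  n_seg <- segmentation$n_segments
  perturb <- function(mask) {
    out <- tensor
    for (cell in which(mask == 1)) {
      row <- (cell - 1L) %/% n_seg + 1L
      seg <- (cell - 1L) %% n_seg + 1L
      out[row, br$start[seg]:br$end[seg]] <- 0
    }
    out
  }
  list(masks = masks, perturb = perturb)
}

#' Explain a model prediction with time-series LIME
#'
#' Generates perturbed copies of one tensor, obtains the model probability
#' for each, fits an ordinary least-squares surrogate of the probabilities
#' on the perturbation masks, and ranks the (row, segment) cells by the
#' magnitude of their surrogate coefficients.  The top 20% (by |coef|,
#' `ceil(0.2 x cells)`) are flagged influential.
#'
#' @param predict_fun Function mapping a rows x samples matrix to a scalar
#'   probability (e.g. wrapping [predict_cnn()]).
#' @param tensor Rows x samples matrix to explain.
#' @param segmentation A [lime_segmentation()].
#' @param n_samples Number of perturbed copies (default `4 x` cell count).
#' @param seed Optional integer seed.
#' @param top_frac Fraction flagged influential (default 0.2).
#' @return A `lime_explanation`: data frame (row, segment, coefficient,
#'   influential) plus attributes `intercept` and `segmentation`.
#' @export
lime_explain <- function(predict_fun, tensor, segmentation,
                         n_samples = NULL, seed = NULL, top_frac = 0.2) {
  n_cells <- segmentation$n_rows * segmentation$n_segments
  if (is.null(n_samples)) n_samples <- 4L * n_cells
  pert <- lime_perturb(tensor, segmentation, n_samples, seed)
  probs <- vapply(seq_len(n_samples),
                  function(i) predict_fun(pert$perturb(pert$masks[i, ])),
                  0)
  X <- cbind(1, pert$masks)
  xtx <- crossprod(X)
  if (rcond_sym(xtx) < 1e-12)
    stop("singular surrogate design; increase n_samples")
  beta <- solve(xtx, crossprod(X, probs))
  coefs <- beta[-1]
  k <- ceiling(top_frac * n_cells)
  flagged <- rank(-abs(coefs), ties.method = "first") <= k
  n_seg <- segmentation$n_segments
  out <- data.frame(row = (seq_len(n_cells) - 1L) %/% n_seg + 1L,
                    segment = (seq_len(n_cells) - 1L) %% n_seg + 1L,
                    coefficient = coefs, influential = flagged)
  attr(out, "intercept") <- beta[1]
  attr(out, "segmentation") <- segmentation
  class(out) <- c("lime_explanation", "data.frame")
  out
}

rcond_sym <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Aggregate explanations across trials
#'
#' Counts, per (row, segment) cell, in how many trials the cell was
#' flagged influential, ranking time segments and electrodes by their
#' frequency of significance.
#'
#' @param explanations List of `lime_explanation`s sharing one
#'   segmentation.
#' @return Data frame (row, segment, frequency).
#' @export
lime_aggregate <- function(explanations) {
  stopifnot(length(explanations) >= 1)
  ref <- attr(explanations[[1]], "segmentation")
  for (e in explanations) {
    s <- attr(e, "segmentation")
    if (s$n_rows != ref$n_rows || s$n_segments != ref$n_segments)
      stop("explanations use different segmentations")
  }
  freq <- Reduce(`+`, lapply(explanations,
                             function(e) as.integer(e$influential)))
  out <- explanations[[1]][, c("row", "segment")]
  out$frequency <- freq
  out
}
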