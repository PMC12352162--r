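#' Build per-channel convolved burst rows for a whole session
#'
#' Runs band-wise burst detection on every channel of a (standardized)
#' recording and renders the convolved high-gamma and beta series, stacked
#' contact-major: row 1 = channel 1 HG, row 2 = channel 1 beta, row 3 =
#' channel 2 HG, ...  This fixed row ordering is what all burst tensors
#' use.
#'
#' @param signal Channels x samples matrix at the 500 Hz analysis rate.
#' @param fs_hz Sampling rate, Hz.
#' @param z_thresh Burst seed threshold (default 2).
#' @param w_scale Gaussian width multiplier, see [convolve_bursts()].
#' @return List: `conv` (2 * n_channels x samples matrix), `bursts` (all
#'   detected events), `fs_hz`.
#' @export
session_convolved <- function(signal, fs_hz = attr(signal, "fs_hz"),
                              z_thresh = 2, w_scale = 1) {
  stopifnot(is.matrix(signal), !is.null(fs_hz))
  n <- ncol(signal)
  chn <- rownames(signal) %||% as.character(seq_len(nrow(signal)))
  conv <- matrix(0, 2 * nrow(signal), n)
  rn <- character(2 * nrow(signal))
  all_b <- list()
  for (ch in seq_len(nrow(signal))) {
    for (bi in 1:2) {
      band <- c("HG", "beta")[bi]
      ev <- detect_bursts_channel(signal[ch, ], fs_hz, band,
                                  z_thresh = z_thresh, channel = chn[ch])
      row <- 2 * (ch - 1) + bi
      conv[row, ] <- as.numeric(
        convolve_bursts(ev, n, fs_hz, w_scale = w_scale))
      rn[row] <- paste0(chn[ch], ".", band)
      all_b[[length(all_b) + 1L]] <- ev
    }
  }
  rownames(conv) <- rn
  list(conv = conv, bursts = do.call(rbind, all_b), fs_hz = fs_hz)
}

new_labeled_dataset <- function(tensors, labels, trial_id, kind, fs_hz,
                                group = NULL) {
  stopifnot(is.array(tensors), length(dim(tensors)) == 3,
            dim(tensors)[3] == length(labels),
            length(trial_id) == length(labels))
  if (is.null(group)) group <- seq_along(labels)
  stopifnot(length(group) == length(labels))
  structure(list(tensors = tensors, labels = as.integer(labels),
                 trial_id = trial_id, kind = kind, fs_hz = fs_hz,
                 group = group),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$tensors)
  cat(sprintf(
    "Labeled dataset (%s): %d tensors of %d x %d @ %g Hz, class balance %.2f\n",
    x$kind, d[3], d[1], d[2], x$fs_hz, mean(x$labels)))
  invisible(x)
}

#' Number of trials in a dataset
#' @param dataset A `labeled_dataset`.
#' @return Integer.
#' @export
n_trials <- function(dataset) dim(dataset$tensors)[3]

# cut one window from a row-stacked signal matrix, with optional decimation
cut_window <- function(mat, fs, onset_s, window_s, decimate) {
  i0 <- round(onset_s * fs) + 1L
  i1 <- i0 + round(window_s * fs) - 1L
  if (i1 > ncol(mat)) return(NULL)
  w <- mat[, i0:i1, drop = FALSE]
  if (decimate > 1L) {
    keep <- seq(1L, ncol(w), by = decimate)
    w <- w[, keep, drop = FALSE]
  }
  w
}

#' Extract labeled stimulus-locked encoding epochs
#'
#' One tensor per word event, starting at word onset and `window_s` long
#' (default 3 s: the 1.6 s word, the inter-stimulus interval, and a margin
#' into the next onset).  Labels are the subsequent-recall flags.  Burst
#' tensors have 2 rows per contact (HG then beta); broadband tensors one
#' row per contact.  Rows are decimated by `decimate` (default 10: 500 Hz
#' convolved series -> 50 Hz CNN input; the Gaussian kernels are smooth at
#' that rate).
#'
#' @param session A `synthetic_session` (or any list with `$schedule` and
#'   `$recalled`).
#' @param conv Row-stacked signal matrix at `fs_hz` (convolved rows from
#'   [session_convolved()], or broadband channels for the raw-iEEG
#'   decoder).
#' @param fs_hz Sampling rate of `conv`.
#' @param window_s Epoch length, s.
#' @param decimate Integer decimation factor for the CNN input.
#' @param kind Tensor kind label (`"ENC_BURST"` or `"ENC_BROADBAND"`).
#' @return A `labeled_dataset`.  Epochs extending past the recording end
#'   are dropped with a warning.
#' @export
extract_encoding_epochs <- function(session, conv, fs_hz = 500,
                                    window_s = 3.0, decimate = 10L,
                                    kind = "ENC_BURST") {
  words <- session$schedule$words
  stopifnot(nrow(words) >= 1, length(session$recalled) == nrow(words))
  tl <- list(); labs <- integer(); ids <- integer(); dropped <- 0L
  for (i in seq_len(nrow(words))) {
    w <- cut_window(conv, fs_hz, words$onset_s[i], window_s, decimate)
    if (is.null(w)) { dropped <- dropped + 1L; next }
    tl[[length(tl) + 1L]] <- w
    labs <- c(labs, as.integer(session$recalled[i]))
    ids <- c(ids, i)
  }
  if (dropped) warning(dropped, " epoch(s) extended past the recording end")
  tensors <- simplify2array(tl)
  new_labeled_dataset(tensors, labs, ids, kind, fs_hz / decimate,
                      group = words$list_index[ids])
}

#' Extract random 3-s segments from the free-recall windows
#'
#' Per list, `per_list` segments with onsets uniform over
#' `[recall_start, recall_end - window_s]`, labeled as recall (0 in the
#' state dataset convention).  Segments may overlap.
#'
#' @inheritParams extract_encoding_epochs
#' @param per_list Segments per list (default chosen by callers to balance
#'   classes against the encoding set).
#' @param seed Optional integer seed for the onset draws.
#' @return A `labeled_dataset` of kind `"STATE_SEGMENT"` with labels 0.
#' @export
extract_recall_segments <- function(session, conv, fs_hz = 500,
                                    window_s = 3.0, per_list = 12L,
                                    seed = NULL, decimate = 10L) {
  recalls <- session$schedule$recalls
  stopifnot(nrow(recalls) >= 1)
  if (!is.null(seed)) set.seed(seed)
  tl <- list(); ids <- integer(); grp <- integer()
  for (l in seq_len(nrow(recalls))) {
    lo <- recalls$onset_s[l]
    hi <- recalls$onset_s[l] + recalls$duration_s[l] - window_s
    for (j in seq_len(per_list)) {
      on <- runif(1, lo, hi)
      w <- cut_window(conv, fs_hz, on, window_s, decimate)
      if (is.null(w)) next
      tl[[length(tl) + 1L]] <- w
      ids <- c(ids, 1000L * l + j)
      grp <- c(grp, recalls$list_index[l])
    }
  }
  tensors <- simplify2array(tl)
  new_labeled_dataset(tensors, rep(0L, length(tl)), ids, "STATE_SEGMENT",
                      fs_hz / decimate, group = grp)
}

#' Pool encoding and recall tensors into a state-decoding dataset
#'
#' Encoding tensors are labeled 1, recall segments 0, and the pooled set is
#' shuffled.  The multiset of tensors is independent of the seed; only the
#' order changes.
#'
#' @param encoding,recall `labeled_dataset`s with matching tensor shapes.
#' @param seed Optional integer seed for the shuffle.
#' @return A `labeled_dataset` of kind `"STATE"`.
#' @export
build_state_dataset <- function(encoding, recall, seed = NULL) {
  de <- dim(encoding$tensors); dr <- dim(recall$tensors)
  if (!all(de[1:2] == dr[1:2]))
    stop("tensor shapes differ between encoding and recall sets")
  if (de[3] == 0 || dr[3] == 0) stop("both classes must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  tensors <- array(0, c(de[1], de[2], de[3] + dr[3]))
  tensors[, , seq_len(de[3])] <- encoding$tensors
  tensors[, , de[3] + seq_len(dr[3])] <- recall$tensors
  labels <- c(rep(1L, de[3]), rep(0L, dr[3]))
  ids <- c(paste0("enc", encoding$trial_id), paste0("rec", recall$trial_id))
  grp <- c(encoding$group, recall$group)
  ord <- sample(length(labels))
  new_labeled_dataset(tensors[, , ord, drop = FALSE], labels[ord], ids[ord],
                      "STATE", encoding$fs_hz, group = grp[ord])
}

#' Smallest modal value of an integer vector
#' @keywords internal
mode_smallest <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[tab == max(tab)][1])
}

#' Extract whole 30-s recall epochs labeled good vs. poor
#'
#' One tensor per list covering the entire free-recall window.  A list is
#' labeled good (1) iff its recall count strictly exceeds the mode of the
#' recall counts across sessions; modal ties are broken toward the smaller
#' value.
#'
#' @inheritParams extract_encoding_epochs
#' @return A `labeled_dataset` of kind `"RECALL_EPOCH"`.  Errors if all
#'   labels are identical (dataset unusable for training).
#' @export
extract_recall_epochs <- function(session, conv, fs_hz = 500,
                                  decimate = 10L) {
  recalls <- session$schedule$recalls
  if (nrow(recalls) < 2) stop("at least 2 lists are required")
  counts <- session$recall_counts
  m <- mode_smallest(counts)
  labels <- as.integer(counts > m)
  if (length(unique(labels)) < 2)
    stop("all recall epochs share one label; dataset rejected for training")
  tl <- list()
  for (l in seq_len(nrow(recalls))) {
    w <- cut_window(conv, fs_hz, recalls$onset_s[l], recalls$duration_s[l],
                    decimate)
    if (is.null(w)) stop("recall epoch ", l, " extends past the recording")
    tl[[l]] <- w
  }
  new_labeled_dataset(simplify2array(tl), labels, seq_len(nrow(recalls)),
                      "RECALL_EPOCH", fs_hz / decimate,
                      group = recalls$list_index)
}

#' Drop the beta rows of a burst dataset
#'
#' Removes every beta row (even rows in the contact-major HG/beta
#' ordering), leaving one HG row per contact; HG rows are untouched.
#'
#' @param dataset A `labeled_dataset` of a burst kind.
#' @return The ablated `labeled_dataset`.
#' @export
ablate_beta <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (identical(dataset$kind, "ENC_BROADBAND"))
    stop("beta ablation applies to burst tensors, not broadband tensors")
  d <- dim(dataset$tensors)
  if (d[1] %% 2 != 0)
    stop("burst tensors must have an even number of rows (HG/beta pairs)")
  keep <- seq(1L, d[1], by = 2L)
  new_labeled_dataset(dataset$tensors[keep, , , drop = FALSE],
                      dataset$labels, dataset$trial_id,
                      paste0(dataset$kind, "_HG_ONLY"), dataset$fs_hz,
                      group = dataset$group)
}
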