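# Shared fixtures, all generated in code under fixed seeds.

# a small labeled dataset of burst-like tensors with an optional mean shift
# on the HG rows of the positive class (no detection pipeline involved)
make_toy_dataset <- function(n = 60, n_rows = 4, T = 75, shift = 0,
                             balance = 0.5, seed = 1) {
  set.seed(seed)
  labels <- rbinom(n, 1, balance)
  # guarantee both classes
  labels[1] <- 0L; labels[2] <- 1L
  x <- array(abs(rnorm(n_rows * T * n, 0.2, 0.2)), c(n_rows, T, n))
  hg_rows <- seq(1, n_rows, by = 2)
  for (i in which(labels == 1))
    x[hg_rows, , i] <- x[hg_rows, , i] + shift
  memburst:::new_labeled_dataset(x, labels, seq_len(n), "ENC_BURST", 25)
}

# one standardized channel of pink noise with planted Hann bursts; returns
# the signal and the truth table
make_burst_channel <- function(duration_s = 10, fs = 500, band = "HG",
                               n_bursts = 3, amp_sd_mult = 8, seed = 1,
                               dur_s = NULL, freq = NULL) {
  set.seed(seed)
  bg <- memburst:::one_over_f_noise(duration_s * fs, fs, -2)
  bg <- bg / sd(bg)
  dur_s <- dur_s %||% if (band == "HG") 0.10 else 0.15
  lim <- band_limits(band)
  onsets <- seq(1, duration_s - 1, length.out = n_bursts + 2)[2:(n_bursts + 1)]
  truth <- data.frame(onset_s = onsets, offset_s = onsets + dur_s,
                      peak_freq_hz = freq %||%
                        runif(n_bursts, lim[1] + 10, lim[2] - 10))
  for (i in seq_len(n_bursts)) {
    idx <- (round(truth$onset_s[i] * fs) + 1):round(truth$offset_s[i] * fs)
    tt <- (idx - idx[1]) / fs
    hann <- 0.5 * (1 - cos(2 * pi * tt / dur_s))
    bg[idx] <- bg[idx] +
      amp_sd_mult * hann * sin(2 * pi * truth$peak_freq_hz[i] * tt)
  }
  list(signal = bg, truth = truth, fs = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Match detected events to truth rows by temporal overlap: a truth burst
# counts as recovered when some event covers at least `min_frac` of its
# extent (the detector's noise-event floor makes proximity-only matching
# meaningless).  Returns a data frame: truth row index + matched event row.
match_bursts <- function(events, truth, min_frac = 0.3) {
  out <- NULL
  for (i in seq_len(nrow(truth))) {
    if (nrow(events) == 0) next
    ov <- pmin(events$offset_s, truth$offset_s[i]) -
      pmax(events$onset_s, truth$onset_s[i])
    j <- which.max(ov)
    if (ov[j] >= min_frac * (truth$offset_s[i] - truth$onset_s[i]))
      out <- rbind(out, data.frame(truth_row = i, event_row = j))
  }
  out %||% data.frame(truth_row = integer(), event_row = integer())
}
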