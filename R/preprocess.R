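#' Define a channel layout of contact groups
#'
#' Contacts within a group must be listed in physical order along the
#' strip, grid row, or depth probe; bipolar referencing subtracts adjacent
#' pairs within each group.
#'
#' @param groups Named list; each element a character vector of contact
#'   names (matching `rownames(signal)`) in physical order.
#' @return A `channel_layout`.
#' @export
channel_layout <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  structure(list(groups = groups), class = "channel_layout")
}

#' Convert referential contacts to a bipolar montage
#'
#' Within each contact group, output channel i is contact i minus contact
#' i + 1, so a group of n contacts yields n - 1 bipolar channels.  Groups
#' with a single contact are skipped with a warning.
#'
#' @param signal Contacts x samples matrix with contact rownames.
#' @param layout A [channel_layout()].
#' @return Bipolar channels x samples matrix; rownames `"a-b"`.
#' @export
to_bipolar <- function(signal, layout) {
  stopifnot(is.matrix(signal), inherits(layout, "channel_layout"))
  rows <- list()
  nms <- character()
  for (g in layout$groups) {
    missing <- setdiff(g, rownames(signal))
    if (length(missing))
      stop("contacts not present in signal: ", paste(missing, collapse = ", "))
    if (length(g) < 2) {
      warning("group with a single contact skipped: ", g[1])
      next
    }
    for (i in seq_len(length(g) - 1L)) {
      rows[[length(rows) + 1L]] <- signal[g[i], ] - signal[g[i + 1L], ]
      nms <- c(nms, paste0(g[i], "-", g[i + 1L]))
    }
  }
  if (!length(rows)) stop("no bipolar channels could be derived")
  out <- do.call(rbind, rows)
  rownames(out) <- nms
  attr(out, "fs_hz") <- attr(signal, "fs_hz")
  out
}

#' Remove 60 Hz line noise
#'
#' Fourth-order Butterworth band-stop with a 2 Hz stop-band centred on
#' 60 Hz (59--61 Hz), applied zero-phase (forward-backward) so burst
#' timing is preserved.
#'
#' @param signal Channels x samples matrix, or a numeric vector.
#' @param fs_hz Sampling rate; must exceed 120 Hz.
#' @return Filtered signal, same shape.
#' @export
notch_60 <- function(signal, fs_hz = attr(signal, "fs_hz")) {
  if (is.null(fs_hz) || fs_hz <= 120)
    stop("`fs_hz` must be > 120 for a 60 Hz notch")
  bt <- signal::butter(4, c(59, 61) / (fs_hz / 2), type = "stop")
  apply_rows(signal, function(x) signal::filtfilt(bt, x))
}

#' Standardize each channel to zero mean, unit variance
#'
#' Standardization is computed over the full recording (per session, per
#' channel).  Constant channels cannot be standardized; they are dropped
#' with a warning and listed in the `excluded` attribute.
#'
#' @param signal Channels x samples matrix, or a numeric vector.
#' @return Standardized signal; attribute `excluded` names dropped
#'   channels.
#' @export
standardize_signal <- function(signal) {
  if (is.null(dim(signal))) {
    s <- stats::sd(signal)
    if (s == 0 || !is.finite(s)) stop("constant channel cannot be standardized")
    return((signal - mean(signal)) / s)
  }
  sds <- apply(signal, 1, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    warning("excluding constant channel(s): ",
            paste(rownames(signal)[bad] %||% bad, collapse = ", "))
  }
  keep <- setdiff(seq_len(nrow(signal)), bad)
  out <- (signal[keep, , drop = FALSE] - rowMeans(signal[keep, , drop = FALSE])) /
    sds[keep]
  attr(out, "fs_hz") <- attr(signal, "fs_hz")
  attr(out, "excluded") <- rownames(signal)[bad] %||% bad
  out
}

#' Automated low-voltage quality screen
#'
#' Band-pass filters each channel in the high-gamma (80--200 Hz) and beta
#' (15--40 Hz) bands with zero-phase FIR filters, computes the RMS in a
#' sliding 200 ms window (100 ms hop), and flags channels whose maximum
#' windowed RMS falls below 5 uV (high-gamma) or 10 uV (beta).  Such
#' channels plausibly sit in white matter or have abnormal impedance.  The
#' input must be in physical microvolts, before standardization.
#'
#' @param signal_uv Channels x samples matrix, uV.
#' @param fs_hz Sampling rate, Hz.
#' @param window_s RMS window (default 0.2 s).
#' @param hop_s Window hop (default 0.1 s).
#' @return A `qc_report` data frame: channel, max_rms_hg_uv,
#'   max_rms_beta_uv, flagged_low_hg, flagged_low_beta.
#' @export
screen_low_voltage <- function(signal_uv, fs_hz = attr(signal_uv, "fs_hz"),
                               window_s = 0.2, hop_s = 0.1) {
  if (is.null(dim(signal_uv))) signal_uv <- matrix(signal_uv, nrow = 1)
  if (is.null(fs_hz)) stop("`fs_hz` is required")
  if (ncol(signal_uv) < window_s * fs_hz)
    stop("recording shorter than the ", window_s * 1000, " ms RMS window")
  hg <- fir_bandpass_mat(signal_uv, fs_hz, band_limits("HG"), order = 300)
  be <- fir_bandpass_mat(signal_uv, fs_hz, band_limits("beta"), order = 100)
  wl <- round(window_s * fs_hz)
  hp <- round(hop_s * fs_hz)
  max_rms <- function(x) {
    starts <- seq(1, length(x) - wl + 1, by = hp)
    max(vapply(starts, function(s) sqrt(mean(x[s:(s + wl - 1)]^2)), 0))
  }
  rms_hg <- apply(hg, 1, max_rms)
  rms_be <- apply(be, 1, max_rms)
  out <- data.frame(
    channel = rownames(signal_uv) %||% as.character(seq_len(nrow(signal_uv))),
    max_rms_hg_uv = rms_hg, max_rms_beta_uv = rms_be,
    flagged_low_hg = rms_hg < 5, flagged_low_beta = rms_be < 10)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Resample channels to a common analysis rate
#'
#' Sessions recorded at 512--2000 Hz are brought to the 500 Hz analysis
#' rate used for burst detection and fixed-size CNN inputs.  Resampling is
#' done in the Fourier domain (spectrum truncation), which is zero-phase
#' and introduces no fractional delay.
#'
#' @param signal Channels x samples matrix or vector.
#' @param fs_from Original sampling rate, Hz.
#' @param fs_to Target rate (default 500 Hz).
#' @return Resampled signal with updated `fs_hz` attribute.
#' @export
resample_to <- function(signal, fs_from = attr(signal, "fs_hz"),
                        fs_to = 500) {
  if (is.null(fs_from)) stop("`fs_from` is required")
  if (fs_from == fs_to) return(signal)
  n_in <- if (is.null(dim(signal))) length(signal) else ncol(signal)
  n_out <- round(n_in * fs_to / fs_from)
  out <- apply_rows(signal, function(x) fft_resample(x, n_out))
  attr(out, "fs_hz") <- fs_to
  out
}

# Fourier-domain resampling: keep the common low-frequency bins, drop (or
# zero-fill) the rest, inverse transform at the new length
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  h <- (min(n, n_out) - 1) %/% 2   # retained bins on each side of DC
  Y <- vector("complex", n_out)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 0) Y[(n_out - h + 1):n_out] <- X[(n - h + 1):n]
  Re(fft(Y, inverse = TRUE)) / n
}

# apply a 1-D filter function over the rows of a matrix (or to a vector),
# preserving rownames and the fs attribute
apply_rows <- function(signal, fun) {
  if (is.null(dim(signal))) return(fun(signal))
  out <- t(apply(signal, 1, fun))
  rownames(out) <- rownames(signal)
  attr(out, "fs_hz") <- attr(signal, "fs_hz")
  out
}

# zero-phase symmetric FIR band-pass over matrix rows: filter then shift by
# the (integer) group delay of the linear-phase kernel
fir_bandpass_mat <- function(signal, fs, band, order) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  h <- as.numeric(signal::fir1(order, band / (fs / 2), type = "pass"))
  half <- order / 2
  t(apply(signal, 1, function(x) {
    y <- signal::filter(h, 1, c(x, rep(0, half)))
    as.numeric(y[(half + 1):(half + length(x))])
  }))
}
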