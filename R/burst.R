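#' Detection frequency grids
#'
#' Burst detection runs on grids wider than the strict bands so that
#' contours of band-edge bursts are not truncated: 50--250 Hz in 4 Hz steps
#' for high-gamma, 5--50 Hz in 1 Hz steps for beta.  Events whose peak
#' frequency falls outside the strict band (80--200 or 15--40 Hz) are
#' discarded afterwards.
#'
#' @param band `"HG"` or `"beta"`.
#' @return Numeric vector of grid frequencies, Hz.
#' @export
detection_grid <- function(band) {
  switch(band,
         HG = seq(50, 250, by = 4),
         beta = seq(5, 50, by = 1),
         stop("unknown band: ", band))
}

#' Morlet n-cycles used per band (7 for high-gamma, 5 for beta)
#' @param band `"HG"` or `"beta"`.
#' @return Integer.
#' @export
band_n_cycles <- function(band) switch(band, HG = 7, beta = 5,
                                       stop("unknown band: ", band))

#' Morlet wavelet time-frequency transform
#'
#' Complex Morlet transform computed by frequency-domain convolution: for
#' each grid frequency f the signal spectrum is multiplied by a one-sided
#' Gaussian of temporal standard deviation `n_cycles / (2 pi f)` centred on
#' f (peak gain 1), and the squared magnitude of the analytic result is
#' returned.
#'
#' @param x Numeric vector, one channel.
#' @param fs_hz Sampling rate, Hz.
#' @param freqs_hz Frequency grid; all entries must be below Nyquist.
#' @param n_cycles Wavelet width in cycles (>= 3).
#' @param decim Integer output decimation.  The analytic (one-sided)
#'   transform of a low band can be sampled at a reduced rate without
#'   aliasing as long as the kernels' spectral support stays below
#'   `fs_hz / decim`; used to speed up beta-band maps.
#' @return Matrix, `length(freqs_hz)` x `ceiling(length(x) / decim)`, of
#'   magnitude^2 values; attributes `freqs_hz` and `fs_hz` (the output
#'   rate) carry the geometry.
#' @export
wavelet_tfr <- function(x, fs_hz, freqs_hz, n_cycles = 7, decim = 1L) {
  stopifnot(is.numeric(x), n_cycles >= 3, decim >= 1)
  if (any(freqs_hz >= fs_hz / 2))
    stop("all frequencies must be below Nyquist (", fs_hz / 2, " Hz)")
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  xf <- fft(c(x, rep(0, nfft - n)))
  f <- seq(0, fs_hz, length.out = nfft + 1)[seq_len(nfft)]
  df <- fs_hz / nfft
  n_half <- floor(fs_hz / 2 / df) + 1L  # last non-negative-frequency bin
  m <- nfft %/% decim                   # reduced-rate transform length
  n_out <- ceiling(n / decim)
  # spectral support of each kernel: 5 sigma_f = 5 f0 / n_cycles
  w_max <- max(freqs_hz) * (1 + 5 / n_cycles)
  if (decim > 1 && w_max >= fs_hz / decim)
    stop("decim too large: kernel support ", round(w_max), " Hz exceeds ",
         fs_hz / decim, " Hz")
  tfr <- matrix(0, length(freqs_hz), n_out)
  g <- vector("complex", m)             # reused kernel buffer
  prev <- integer(0)
  for (i in seq_along(freqs_hz)) {
    f0 <- freqs_hz[i]
    sigma_t <- n_cycles / (2 * pi * f0)
    w <- 5 / (2 * pi * sigma_t)         # 5 sigma_f truncation
    sup <- max(1L, ceiling((f0 - w) / df) + 1L):
      min(n_half, m, floor((f0 + w) / df) + 1L)
    g[prev] <- 0
    g[sup] <- exp(-0.5 * ((f[sup] - f0) * 2 * pi * sigma_t)^2) * xf[sup]
    prev <- sup
    y <- fft(g, inverse = TRUE)[seq_len(n_out)] / nfft
    tfr[i, ] <- Re(y)^2 + Im(y)^2
  }
  attr(tfr, "freqs_hz") <- freqs_hz
  attr(tfr, "fs_hz") <- fs_hz / decim
  tfr
}

#' Detect oscillatory bursts by topographical analysis of the wavelet map
#'
#' Each frequency row of the time-frequency map is z-scored across time
#' (per-frequency baseline normalization).  Local maxima with z at or above
#' `z_thresh` seed bursts; every seed is expanded to its half-maximum
#' contour by flood fill in the z-scored map (stronger seeds claim cells
#' first).  A burst's onset/offset are the temporal extent of its contour,
#' its peak frequency is the seed's frequency, and its power is the summed
#' magnitude^2 inside the contour.  Events whose peak frequency falls
#' outside the strict band are discarded and overlapping same-band events
#' are merged (union of extents; the stronger seed's frequency; summed
#' power).
#'
#' @param tfr Magnitude^2 matrix from [wavelet_tfr()] on the matching
#'   [detection_grid()].
#' @param band `"HG"` or `"beta"`: sets the strict band filter.
#' @param z_thresh Seed threshold in z units (default 2).
#' @param fs_hz,freqs_hz Sampling rate and grid; taken from `tfr`
#'   attributes when present.
#' @param channel Channel name recorded in the output.
#' @param merge `"proximal"` (default) merges overlapping events only when
#'   their peak frequencies lie within the wavelet's spectral resolution
#'   (fragments of one burst); `"time"` merges all temporally overlapping
#'   same-band events.
#' @param baseline_q Quantile of each frequency row used as the baseline
#'   cut: statistics are computed from cells at or below it.  The default
#'   0.75 tolerates bursts occupying up to a quarter of the recording;
#'   a higher cut lets dense burst activity inflate its own baseline and
#'   mask detection.
#' @return Data frame of `burst_events`: channel, band, onset_s, offset_s,
#'   duration_s, peak_freq_hz, power.
#' @export
detect_bursts <- function(tfr, band = c("HG", "beta"), z_thresh = 2,
                          fs_hz = attr(tfr, "fs_hz"),
                          freqs_hz = attr(tfr, "freqs_hz"),
                          channel = "ch1",
                          merge = c("proximal", "time"),
                          baseline_q = 0.75) {
  merge <- match.arg(merge)
  band <- match.arg(band)
  if (length(tfr) == 0 || nrow(tfr) == 0)
    return(empty_bursts())
  stopifnot(!is.null(fs_hz), !is.null(freqs_hz),
            length(freqs_hz) == nrow(tfr))
  # robust per-frequency baseline: mean/sd of the cells at or below the
  # baseline quantile, so that the bursts being detected do not inflate
  # their own row's baseline (which would deflate their z and let weak
  # spectral leakage into quiet rows dominate the seed ordering)
  mu <- numeric(nrow(tfr))
  sdv <- numeric(nrow(tfr))
  # baseline statistics from a deterministic subsample (>= 10k cells):
  # estimator noise is negligible at these lengths and the partial sorts
  # dominate detection cost otherwise
  stride <- max(1L, ncol(tfr) %/% 10000L)
  cols <- seq(1L, ncol(tfr), by = stride)
  for (r in seq_len(nrow(tfr))) {
    row <- tfr[r, cols]
    base <- row[row <= stats::quantile(row, baseline_q, names = FALSE)]
    mu[r] <- mean(base)
    sdv[r] <- stats::sd(base)
  }
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf  # flat rows produce no seeds
  z <- (tfr - mu) / sdv
  # baseline-relative excess drives the half-maximum contour expansion
  mu_rel <- ifelse(mu > 0, mu, Inf)
  rel <- (tfr - mu) / mu_rel
  ev <- detect_bursts_core(z, tfr, rel, z_thresh)
  if (nrow(ev) == 0) return(empty_bursts())
  out <- data.frame(channel = channel, band = band,
                    onset_s = (ev[, 3] - 1) / fs_hz,
                    offset_s = ev[, 4] / fs_hz,
                    peak_freq_hz = freqs_hz[ev[, 1]],
                    power = ev[, 5], seed_z = ev[, 6])
  lim <- band_limits(band)
  out <- out[out$peak_freq_hz >= lim[1] & out$peak_freq_hz <= lim[2], ,
             drop = FALSE]
  out <- merge_overlapping(out, n_cycles = if (merge == "proximal")
    band_n_cycles(band) else Inf)
  out$duration_s <- out$offset_s - out$onset_s
  rownames(out) <- NULL
  out[, c("channel", "band", "onset_s", "offset_s", "duration_s",
          "peak_freq_hz", "power")]
}

empty_bursts <- function() {
  data.frame(channel = character(), band = character(), onset_s = numeric(),
             offset_s = numeric(), duration_s = numeric(),
             peak_freq_hz = numeric(), power = numeric())
}

# Merge same-band events that overlap in time AND lie within the
# wavelet's spectral resolution of each other (2 sigma_f = 2 f / n_cycles
# at the events' mean frequency): such pairs are fragments of one burst
# split by noise.  Distinct co-occurring bursts at well-separated
# frequencies are kept apart -- a time-only merge would conflate them and
# compress burst counts exactly when rates are high.  The merged event
# keeps the dominant (highest-power) component's frequency and sums
# power.  Power, not seed z, decides dominance: z is normalized per
# frequency, so weak leakage into a quiet row can carry a large z.
merge_overlapping <- function(ev, n_cycles = 6) {
  n <- nrow(ev)
  if (n < 2) return(ev)
  ord <- order(ev$onset_s)
  on <- ev$onset_s[ord]; off <- ev$offset_s[ord]
  fq <- ev$peak_freq_hz[ord]; pw <- ev$power[ord]; sz <- ev$seed_z[ord]
  # preallocated single pass; j indexes the current merged event
  j <- 1L
  dom <- pw[1]
  for (i in 2:n) {
    # 2 sigma_f at the mean frequency; infinite n_cycles = time-only merge
    f_res <- if (is.finite(n_cycles)) (fq[i] + fq[j]) / n_cycles else Inf
    if (on[i] < off[j] && abs(fq[i] - fq[j]) <= f_res) {
      off[j] <- max(off[j], off[i])
      if (pw[i] > dom) {
        fq[j] <- fq[i]; sz[j] <- sz[i]; dom <- pw[i]
      }
      pw[j] <- pw[j] + pw[i]
    } else {
      j <- j + 1L
      on[j] <- on[i]; off[j] <- off[i]; fq[j] <- fq[i]
      pw[j] <- pw[i]; sz[j] <- sz[i]; dom <- pw[i]
    }
  }
  keep <- seq_len(j)
  data.frame(channel = ev$channel[1], band = ev$band[1],
             onset_s = on[keep], offset_s = off[keep],
             peak_freq_hz = fq[keep], power = pw[keep],
             seed_z = sz[keep])
}

#' Detect bursts of one band on a full recording channel
#'
#' Convenience wrapper: computes the wavelet transform on the band's
#' detection grid and runs [detect_bursts()].  Long recordings are
#' processed in chunks (default 120 s with 2 s overlap; per-frequency
#' normalization is per chunk) to bound memory; an event is kept by the
#' chunk that contains its midpoint.
#'
#' @param x Numeric vector (standardized channel, 500 Hz analysis rate).
#' @param fs_hz Sampling rate, Hz.
#' @param band `"HG"` or `"beta"`.
#' @param z_thresh Seed threshold (default 2).
#' @param channel Channel name for the output.
#' @param chunk_s,overlap_s Chunking parameters, s.
#' @return `burst_events` data frame, see [detect_bursts()].
#' @export
detect_bursts_channel <- function(x, fs_hz, band = c("HG", "beta"),
                                  z_thresh = 2, channel = "ch1",
                                  chunk_s = 120, overlap_s = 2,
                                  merge = c("proximal", "time"),
                                  baseline_q = 0.75) {
  band <- match.arg(band)
  merge <- match.arg(merge)
  n <- length(x)
  grid <- detection_grid(band)
  grid <- grid[grid < fs_hz / 2]  # grid tips beyond Nyquist are dropped
  ncyc <- band_n_cycles(band)
  # the beta map fits below fs/4, so its analytic transform is computed at
  # a quarter of the rate
  decim <- if (band == "beta") max(1L, floor(fs_hz / 125)) else 1L
  while (decim > 1 && max(grid) * (1 + 5 / ncyc) >= fs_hz / decim)
    decim <- decim - 1L
  chunk <- round(chunk_s * fs_hz)
  if (n <= chunk + overlap_s * fs_hz) {
    tfr <- wavelet_tfr(x, fs_hz, grid, ncyc, decim)
    return(detect_bursts(tfr, band, z_thresh, channel = channel,
                         merge = merge, baseline_q = baseline_q))
  }
  pad <- round(overlap_s * fs_hz)
  starts <- seq(1, n, by = chunk)
  res <- list()
  for (s in starts) {
    lo <- max(1, s - pad)
    hi <- min(n, s + chunk - 1 + pad)
    tfr <- wavelet_tfr(x[lo:hi], fs_hz, grid, ncyc, decim)
    ev <- detect_bursts(tfr, band, z_thresh, channel = channel,
                        merge = merge, baseline_q = baseline_q)
    if (nrow(ev) == 0) next
    ev$onset_s <- ev$onset_s + (lo - 1) / fs_hz
    ev$offset_s <- ev$offset_s + (lo - 1) / fs_hz
    mid <- (ev$onset_s + ev$offset_s) / 2
    core_lo <- (s - 1) / fs_hz
    core_hi <- min(n, s + chunk - 1) / fs_hz
    res[[length(res) + 1L]] <- ev[mid >= core_lo & mid < core_hi, ,
                                  drop = FALSE]
  }
  if (!length(res)) return(empty_bursts())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Render detected bursts as a Gaussian-kernel time series
#'
#' Each burst contributes `A * exp(-(t - p)^2 / (2 w^2))`, where `A` is the
#' burst's power measure normalized by `power_norm` (default: the median
#' over the burst set, so a typical burst peaks at 1), `p` is the midpoint
#' of onset and offset, and `w` is the burst duration times `w_scale`.
#' Overlapping kernels sum.  Kernels are evaluated on +/- 5 w support, so
#' the series is exactly zero where no kernel has support.
#'
#' The default power measure is the burst's power *density* (contour power
#' divided by duration): the kernel width `w` already encodes duration, so
#' scaling `A` by the duration-summed power would count duration twice and
#' let a few long events dominate the series.  `amplitude = "power"` uses
#' the raw contour-summed power instead.
#'
#' @param bursts `burst_events` data frame (one channel, one band).
#' @param n_samples Output length in samples.
#' @param fs_hz Output sampling rate (default 500 Hz).
#' @param power_norm Normalization constant for amplitudes; `NULL` uses the
#'   median of the chosen power measure over the burst set.
#' @param w_scale Multiplier applied to duration to obtain the Gaussian
#'   width parameter (default 1: width equals duration).
#' @param amplitude `"density"` (default) scales kernels by power /
#'   duration; `"power"` by the contour-summed power.
#' @return Numeric vector of length `n_samples`, class `convolved_series`,
#'   with `fs_hz` attribute.  Empty input yields the zero series.
#' @export
convolve_bursts <- function(bursts, n_samples, fs_hz = 500,
                            power_norm = NULL, w_scale = 1,
                            amplitude = c("density", "power")) {
  amplitude <- match.arg(amplitude)
  values <- numeric(n_samples)
  if (nrow(bursts) > 0) {
    if (length(unique(bursts$band)) > 1)
      stop("`bursts` must contain a single band")
    meas <- if (amplitude == "density")
      bursts$power / pmax(bursts$offset_s - bursts$onset_s, 1e-6)
    else bursts$power
    if (is.null(power_norm)) power_norm <- median(meas)
    if (!is.finite(power_norm) || power_norm <= 0) power_norm <- 1
    p <- (bursts$onset_s + bursts$offset_s) / 2
    w <- (bursts$offset_s - bursts$onset_s) * w_scale
    A <- meas / power_norm
    for (i in seq_len(nrow(bursts))) {
      if (w[i] <= 0) next
      lo <- max(1L, floor((p[i] - 5 * w[i]) * fs_hz) + 1L)
      hi <- min(n_samples, ceiling((p[i] + 5 * w[i]) * fs_hz) + 1L)
      if (hi < lo) next
      tt <- (lo:hi - 1) / fs_hz
      inside <- abs(tt - p[i]) <= 5 * w[i]  # exact +/- 5 w support
      values[lo:hi][inside] <- values[lo:hi][inside] +
        A[i] * exp(-(tt[inside] - p[i])^2 / (2 * w[i]^2))
    }
  }
  structure(values, fs_hz = fs_hz, class = "convolved_series")
}

#' Burst signal-to-noise ratio of one channel
#'
#' Band-pass filters the signal with a symmetric FIR filter (order 500 for
#' high-gamma, 100 for beta), applied zero-phase.  Noise is the RMS of the
#' filtered signal.  Candidate burst peaks are local maxima of the absolute
#' filtered signal (second-derivative sign changes) whose z-score is at
#' least `z_thresh`; the signal amplitude is the 95th percentile of those
#' peak amplitudes, and SNR = signal / noise.  If no peak reaches the z
#' threshold (e.g. a pure sinusoid, where every peak is typical), all local
#' maxima are used instead.
#'
#' @param x Numeric vector, uV (a few seconds minimum).
#' @param fs_hz Sampling rate, Hz.
#' @param band `"HG"` or `"beta"`.
#' @param z_thresh Peak z-score threshold (default 2).
#' @return Scalar SNR.
#' @export
burst_snr <- function(x, fs_hz, band = c("HG", "beta"), z_thresh = 2) {
  band <- match.arg(band)
  if (all(x == 0)) stop("all-zero signal: SNR undefined")
  ord <- if (band == "HG") 500 else 100
  y <- as.numeric(fir_bandpass_mat(x, fs_hz, band_limits(band), ord))
  noise <- sqrt(mean(y^2))
  if (noise == 0) stop("band-filtered signal is zero: SNR undefined")
  env <- abs(y)
  d1 <- diff(env)
  peaks <- which(d1[-length(d1)] > 0 & d1[-1] <= 0) + 1L
  if (!length(peaks)) stop("no peaks found in band-filtered signal")
  zpk <- (env[peaks] - mean(env)) / stats::sd(env)
  sel <- peaks[zpk >= z_thresh]
  if (!length(sel)) sel <- peaks
  as.numeric(quantile(env[sel], 0.95, names = FALSE)) / noise
}

#' Mean burst SNR across the channels of one experiment
#'
#' @param snr_hg,snr_beta Numeric vectors of per-channel SNRs.
#' @return Named list `mean_hg`, `mean_beta`.
#' @export
mean_experiment_snr <- function(snr_hg, snr_beta) {
  stopifnot(length(snr_hg) >= 1, length(snr_beta) >= 1)
  list(mean_hg = mean(snr_hg), mean_beta = mean(snr_beta))
}

#' Write / read burst events as TSV
#' @param bursts `burst_events` data frame.
#' @param path File path.
#' @return `read_bursts_tsv` returns the data frame.
#' @export
write_bursts_tsv <- function(bursts, path) write_tsv(bursts, path)

#' @rdname write_bursts_tsv
#' @export
read_bursts_tsv <- function(path) read_tsv(path)
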