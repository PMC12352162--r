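#' Supported sampling rates
#'
#' The acquisition rates emulated by the synthetic generator (Hz).
#' @keywords internal
SUPPORTED_FS <- c(500, 512, 1000, 1024, 2000)

#' Generate a delayed free-recall task schedule
#'
#' Builds the temporal structure of a delayed verbal free-recall session:
#' per list, 12 words are presented for 1.6 s each, separated by a blank
#' inter-stimulus interval drawn uniformly from \[0.75, 1\] s; an arithmetic
#' distractor (20 s) starts immediately after the 12th word, and a 30 s free
#' recall window immediately after the distractor.
#'
#' @param n_lists Number of word lists (>= 1).
#' @param seed Optional integer seed for the ISI draws.
#' @param n_words Words per list (default 12).
#' @param word_duration_s On-screen word duration in seconds (default 1.6).
#' @param isi_range_s Two-element range of the inter-stimulus interval, s.
#' @param distractor_s Distractor duration, s (default 20).
#' @param recall_s Free-recall duration, s (default 30).
#' @param lead_in_s Quiet seconds before the first word (default 5).
#' @param inter_list_s Quiet seconds between recall end and the next list
#'   (default 3).
#' @return A `task_schedule`: list with data frames `words` (list_index,
#'   word_index, onset_s, duration_s), `distractors` and `recalls`
#'   (list_index, onset_s, duration_s), and `total_duration_s`.
#' @examples
#' sch <- generate_schedule(2, seed = 1)
#' nrow(sch$words)  # 24
#' @export
generate_schedule <- function(n_lists, seed = NULL, n_words = 12L,
                              word_duration_s = 1.6,
                              isi_range_s = c(0.75, 1.0),
                              distractor_s = 20, recall_s = 30,
                              lead_in_s = 5, inter_list_s = 3) {
  if (!is.numeric(n_lists) || length(n_lists) != 1L || n_lists < 1)
    stop("`n_lists` must be a single integer >= 1")
  n_lists <- as.integer(n_lists)
  if (!is.null(seed)) set.seed(seed)
  words <- vector("list", n_lists)
  distractors <- data.frame(list_index = integer(), onset_s = numeric(),
                            duration_s = numeric())
  recalls <- distractors
  t_cursor <- lead_in_s
  for (l in seq_len(n_lists)) {
    isi <- runif(n_words - 1L, isi_range_s[1], isi_range_s[2])
    onsets <- t_cursor + c(0, cumsum(word_duration_s + isi))
    words[[l]] <- data.frame(list_index = l, word_index = seq_len(n_words),
                             onset_s = onsets, duration_s = word_duration_s)
    d_on <- onsets[n_words] + word_duration_s
    r_on <- d_on + distractor_s
    distractors <- rbind(distractors,
                         data.frame(list_index = l, onset_s = d_on,
                                    duration_s = distractor_s))
    recalls <- rbind(recalls,
                     data.frame(list_index = l, onset_s = r_on,
                                duration_s = recall_s))
    t_cursor <- r_on + recall_s + inter_list_s
  }
  out <- list(words = do.call(rbind, words), distractors = distractors,
              recalls = recalls,
              total_duration_s = t_cursor - inter_list_s + lead_in_s)
  class(out) <- "task_schedule"
  out
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("Delayed free-recall schedule:",
      max(x$words$list_index), "lists,",
      nrow(x$words), "word events,",
      sprintf("%.1f s total\n", x$total_duration_s))
  invisible(x)
}

#' Burst statistics specification for one band
#'
#' Describes the Poisson rate, spectral range, duration and amplitude
#' distributions of planted oscillatory bursts, plus per-class multipliers
#' applied to trials whose word is later recalled.
#'
#' @param band `"HG"` (high-gamma, 80--200 Hz) or `"beta"` (15--40 Hz).
#' @param rate_hz Mean bursts per second per channel inside a trial window.
#' @param dur_mean_s,dur_sd_s Gaussian burst-duration distribution, s
#'   (truncated below at `dur_min_s`).
#' @param amp_mean_uv,amp_sd_uv Gaussian burst-amplitude distribution, uV.
#' @param freq_lo_hz,freq_hi_hz Range the per-burst centre frequency is
#'   drawn from (uniform); must lie within the strict band limits.
#' @param rate_mult,amp_mult Class multipliers applied to the rate and
#'   amplitude for positive-class (recalled) trials.
#' @param dur_min_s Lower truncation for durations, s.
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(band = c("HG", "beta"), rate_hz = 0.6,
                       dur_mean_s = 0.10, dur_sd_s = 0.02,
                       amp_mean_uv = 100, amp_sd_uv = 20,
                       freq_lo_hz = NULL, freq_hi_hz = NULL,
                       rate_mult = 1, amp_mult = 1, dur_min_s = 0.05) {
  band <- match.arg(band)
  lim <- band_limits(band)
  if (is.null(freq_lo_hz)) freq_lo_hz <- lim[1] + 0.05 * diff(lim)
  if (is.null(freq_hi_hz)) freq_hi_hz <- lim[2] - 0.05 * diff(lim)
  stopifnot(rate_hz >= 0, dur_mean_s > 0, amp_mean_uv > 0,
            freq_lo_hz >= lim[1], freq_hi_hz <= lim[2],
            freq_lo_hz <= freq_hi_hz, rate_mult >= 0, amp_mult >= 0)
  structure(list(band = band, rate_hz = rate_hz, dur_mean_s = dur_mean_s,
                 dur_sd_s = dur_sd_s, amp_mean_uv = amp_mean_uv,
                 amp_sd_uv = amp_sd_uv, freq_lo_hz = freq_lo_hz,
                 freq_hi_hz = freq_hi_hz, rate_mult = rate_mult,
                 amp_mult = amp_mult, dur_min_s = dur_min_s),
            class = "burst_spec")
}

#' Strict band limits in Hz
#' @param band `"HG"` or `"beta"`.
#' @return Numeric length-2 vector.
#' @export
band_limits <- function(band) {
  switch(band, HG = c(80, 200), beta = c(15, 40),
         stop("unknown band: ", band))
}

#' Simulate 1/f background iEEG with line noise
#'
#' Each channel is independently generated 1/f-shaped Gaussian noise
#' (power spectral density proportional to f^slope) scaled to a target RMS,
#' plus a 60 Hz sinusoid emulating mains contamination.
#'
#' @param n_channels Number of channels.
#' @param duration_s Recording length, s.
#' @param fs_hz Sampling rate; one of 500, 512, 1000, 1024, 2000.
#' @param line_amp_uv Amplitude of the 60 Hz component, uV (0 disables it).
#' @param slope Log-log PSD slope of the background (default -2).
#' @param rms_uv Target root-mean-square amplitude of the background, uV.
#' @param seed Optional integer seed.
#' @return Matrix, channels x samples, uV.
#' @export
simulate_background <- function(n_channels, duration_s, fs_hz = 500,
                                line_amp_uv = 5, slope = -2, rms_uv = 20,
                                seed = NULL) {
  if (!fs_hz %in% SUPPORTED_FS)
    stop("`fs_hz` must be one of ", paste(SUPPORTED_FS, collapse = ", "))
  stopifnot(duration_s > 0, n_channels >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs_hz)
  tvec <- (seq_len(n) - 1) / fs_hz
  line <- line_amp_uv * sin(2 * pi * 60 * tvec)
  sig <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    x <- one_over_f_noise(n, fs_hz, slope)
    x <- x * (rms_uv / stats::sd(x))
    sig[ch, ] <- x + line
  }
  rownames(sig) <- sprintf("CH%02d", seq_len(n_channels))
  attr(sig, "fs_hz") <- fs_hz
  sig
}

# 1/f^(-slope/2) amplitude shaping of white noise in the frequency domain;
# computed on a padded power-of-two length (FFT cost is O(m log m) only for
# smooth m) and truncated
one_over_f_noise <- function(n, fs, slope) {
  m <- stats::nextn(n, 2)
  white <- rnorm(m)
  xf <- fft(white)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirrored frequencies
  shape <- c(0, f[-1]^(slope / 2))     # kill DC
  (Re(fft(xf * shape, inverse = TRUE)) / m)[seq_len(n)]
}

#' Inject Hann-windowed oscillatory bursts into trial windows
#'
#' Burst onsets follow a Poisson process at `spec$rate_hz` (scaled by the
#' class multiplier for positive-label trials) inside each window; bursts
#' whose extent would cross a window edge are rejected and redrawn, so
#' per-window counts stay Poisson at the scaled rate.  Each burst is a
#' Hann-windowed sinusoid at a centre frequency drawn uniformly from the
#' spec's range.
#'
#' @param signal Channels x samples matrix (uV) with `fs_hz` attribute, or
#'   pass `fs_hz` explicitly.
#' @param windows Data frame with columns `onset_s`, `duration_s` and
#'   optionally `label` (0/1; positive trials get the class multipliers)
#'   and `window_id`.
#' @param spec A [burst_spec()].
#' @param seed Optional integer seed.
#' @param fs_hz Sampling rate, Hz.
#' @return List with `signal` (bursts added) and `truth` (data frame:
#'   channel, band, onset_s, offset_s, peak_freq_hz, amplitude_uv,
#'   window_id).
#' @export
inject_bursts <- function(signal, windows, spec, seed = NULL,
                          fs_hz = attr(signal, "fs_hz")) {
  stopifnot(inherits(spec, "burst_spec"), is.matrix(signal),
            !is.null(fs_hz))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(windows$label)) windows$label <- 0
  if (is.null(windows$window_id)) windows$window_id <- seq_len(nrow(windows))
  n <- ncol(signal)
  truth <- list()
  k <- 0L
  for (ch in seq_len(nrow(signal))) {
    for (w in seq_len(nrow(windows))) {
      mult_r <- if (windows$label[w] == 1) spec$rate_mult else 1
      mult_a <- if (windows$label[w] == 1) spec$amp_mult else 1
      lambda <- spec$rate_hz * mult_r * windows$duration_s[w]
      n_b <- rpois(1, lambda)
      if (n_b == 0) next
      for (b in seq_len(n_b)) {
        for (try in 1:50) {  # rejection: burst must fit inside the window
          dur <- max(spec$dur_min_s, rnorm(1, spec$dur_mean_s, spec$dur_sd_s))
          on <- windows$onset_s[w] + runif(1) * windows$duration_s[w]
          if (on + dur <= windows$onset_s[w] + windows$duration_s[w]) break
        }
        if (on + dur > windows$onset_s[w] + windows$duration_s[w]) next
        f0 <- runif(1, spec$freq_lo_hz, spec$freq_hi_hz)
        amp <- abs(rnorm(1, spec$amp_mean_uv * mult_a, spec$amp_sd_uv))
        i0 <- floor(on * fs_hz) + 1L
        i1 <- min(n, floor((on + dur) * fs_hz))
        if (i1 <= i0) next
        idx <- i0:i1
        tt <- (idx - i0) / fs_hz
        hann <- 0.5 * (1 - cos(2 * pi * tt / dur))
        signal[ch, idx] <- signal[ch, idx] +
          amp * hann * sin(2 * pi * f0 * tt)
        k <- k + 1L
        truth[[k]] <- data.frame(
          channel = rownames(signal)[ch] %||% as.character(ch),
          band = spec$band, onset_s = on, offset_s = on + dur,
          peak_freq_hz = f0, amplitude_uv = amp,
          window_id = windows$window_id[w])
      }
    }
  }
  truth <- if (k > 0) do.call(rbind, truth) else
    data.frame(channel = character(), band = character(),
               onset_s = numeric(), offset_s = numeric(),
               peak_freq_hz = numeric(), amplitude_uv = numeric(),
               window_id = integer())
  list(signal = signal, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic iEEG free-recall session
#'
#' Generates the task schedule, labels each word as subsequently recalled
#' with probability `recall_p`, synthesizes 1/f + line-noise background on
#' bipolar-referenced channels, and plants class-dependent high-gamma and
#' beta bursts inside the 3-s word encoding windows plus a distinct burst
#' regime inside the 30-s recall windows (making memory state decodable).
#' Ground truth (labels and every planted burst) is carried alongside the
#' signal.
#'
#' @param n_lists Number of word lists (default 12).
#' @param n_channels Number of (already bipolar-referenced) channels.
#' @param fs_hz Sampling rate (default 500 Hz).
#' @param recall_p Per-word probability of subsequent recall.
#' @param hg,beta [burst_spec()]s for the encoding-window regimes; their
#'   `rate_mult`/`amp_mult` encode the recalled-vs-forgotten effect.
#' @param recall_rate_hg_hz,recall_rate_beta_hz Burst rates during the
#'   free-recall windows (the recall regime; class multipliers do not apply
#'   there).
#' @param encoding_window_s Length of the trial window bursts are planted
#'   in, from word onset (default 3 s, matching the decoder epochs).
#' @param line_amp_uv,bg_rms_uv,bg_slope Background parameters, see
#'   [simulate_background()].
#' @param seed Integer seed; the session is bit-reproducible given the seed.
#' @return A `synthetic_session`: list with `signal` (channels x samples,
#'   uV), `fs_hz`, `schedule`, `recalled` (logical per word event),
#'   `recall_counts` (per list), `truth_bursts`, and `seed`.
#' @examples
#' s <- simulate_session(n_lists = 1, n_channels = 1, seed = 1)
#' sum(s$recall_counts) == sum(s$recalled)
#' @export
simulate_session <- function(n_lists = 12, n_channels = 2, fs_hz = 500,
                             recall_p = 0.25,
                             hg = burst_spec("HG", rate_hz = 0.6,
                                             dur_mean_s = 0.10,
                                             dur_sd_s = 0.02,
                                             amp_mean_uv = 100,
                                             amp_sd_uv = 20),
                             beta = burst_spec("beta", rate_hz = 0.4,
                                               dur_mean_s = 0.15,
                                               dur_sd_s = 0.03,
                                               amp_mean_uv = 100,
                                               amp_sd_uv = 20),
                             recall_rate_hg_hz = 1.5,
                             recall_rate_beta_hz = 1.0,
                             encoding_window_s = 3.0,
                             line_amp_uv = 5, bg_rms_uv = 20, bg_slope = -2,
                             seed = NULL) {
  stopifnot(recall_p >= 0, recall_p <= 1)
  if (!is.null(seed)) set.seed(seed)
  schedule <- generate_schedule(n_lists)
  recalled <- rbinom(nrow(schedule$words), 1, recall_p)
  recall_counts <- as.integer(tapply(recalled, schedule$words$list_index, sum))

  sig <- simulate_background(n_channels, schedule$total_duration_s, fs_hz,
                             line_amp_uv = line_amp_uv, slope = bg_slope,
                             rms_uv = bg_rms_uv)
  rownames(sig) <- sprintf("LSMG%d-LSMG%d", seq_len(n_channels),
                           seq_len(n_channels) + 1L)

  # burst-planting windows partition the encoding epoch: each word's
  # window runs to the next word onset (capped at encoding_window_s), so
  # windows never overlap and no region is double-planted
  w_on <- schedule$words$onset_s
  w_next <- c(w_on[-1], Inf)
  same_list <- c(diff(schedule$words$list_index) == 0, FALSE)
  w_dur <- ifelse(same_list, pmin(encoding_window_s, w_next - w_on),
                  encoding_window_s)
  enc_win <- data.frame(onset_s = w_on, duration_s = w_dur,
                        label = recalled,
                        window_id = seq_len(nrow(schedule$words)))
  rec_win <- data.frame(onset_s = schedule$recalls$onset_s,
                        duration_s = schedule$recalls$duration_s,
                        label = 0,
                        window_id = -schedule$recalls$list_index)

  out <- inject_bursts(sig, enc_win, hg, fs_hz = fs_hz)
  truth <- out$truth
  out <- inject_bursts(out$signal, enc_win, beta, fs_hz = fs_hz)
  truth <- rbind(truth, out$truth)

  rec_hg <- hg; rec_hg$rate_hz <- recall_rate_hg_hz
  rec_hg$rate_mult <- 1; rec_hg$amp_mult <- 1
  rec_beta <- beta; rec_beta$rate_hz <- recall_rate_beta_hz
  rec_beta$rate_mult <- 1; rec_beta$amp_mult <- 1
  out2 <- inject_bursts(out$signal, rec_win, rec_hg, fs_hz = fs_hz)
  truth <- rbind(truth, out2$truth)
  out2 <- inject_bursts(out2$signal, rec_win, rec_beta, fs_hz = fs_hz)
  truth <- rbind(truth, out2$truth)

  sig <- out2$signal
  attr(sig, "fs_hz") <- fs_hz
  structure(list(signal = sig, fs_hz = fs_hz, schedule = schedule,
                 recalled = as.logical(recalled),
                 recall_counts = recall_counts, truth_bursts = truth,
                 seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "Synthetic iEEG session: %d channel(s) x %.0f s @ %d Hz, %d lists, %d/%d words recalled, %d planted bursts\n",
    nrow(x$signal), ncol(x$signal) / x$fs_hz, x$fs_hz,
    max(x$schedule$words$list_index), sum(x$recalled), length(x$recalled),
    nrow(x$truth_bursts)))
  invisible(x)
}

#' Write a synthetic session in a BIDS-iEEG-style text layout
#'
#' Writes `<prefix>_ieeg.bin` (float32, channel-major interleave: sample 1
#' of every channel, then sample 2, ..., little-endian) with a JSON sidecar,
#' `<prefix>_events.tsv` (onset, duration, trial_type in WORD / DISTRACTOR /
#' REC_START, item, recalled), `<prefix>_channels.tsv`, and
#' `<prefix>_truth_bursts.tsv`.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"session"`).
#' @return Invisibly, the paths written.
#' @export
write_session_bids <- function(session, dir, prefix = "session") {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))

  con <- file(p("_ieeg.bin"), "wb")
  writeBin(as.numeric(session$signal), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(SamplingFrequency = session$fs_hz,
         Channels = rownames(session$signal),
         Samples = ncol(session$signal),
         DataType = "float32", ByteOrder = "little",
         Layout = "column-major channels x samples"),
    p("_ieeg.json"), auto_unbox = TRUE, digits = NA)

  w <- session$schedule$words
  ev <- rbind(
    data.frame(onset = w$onset_s, duration = w$duration_s,
               trial_type = "WORD",
               item = sprintf("L%02dW%02d", w$list_index, w$word_index),
               recalled = as.integer(session$recalled)),
    data.frame(onset = session$schedule$distractors$onset_s,
               duration = session$schedule$distractors$duration_s,
               trial_type = "DISTRACTOR", item = "", recalled = NA),
    data.frame(onset = session$schedule$recalls$onset_s,
               duration = session$schedule$recalls$duration_s,
               trial_type = "REC_START", item = "", recalled = NA))
  ev <- ev[order(ev$onset), ]
  write_tsv(ev, p("_events.tsv"))
  write_tsv(data.frame(name = rownames(session$signal), type = "ECOG",
                       units = "uV",
                       sampling_frequency = session$fs_hz),
            p("_channels.tsv"))
  write_tsv(session$truth_bursts, p("_truth_bursts.tsv"))
  invisible(c(p("_ieeg.bin"), p("_ieeg.json"), p("_events.tsv"),
              p("_channels.tsv"), p("_truth_bursts.tsv")))
}

#' Read a session written by [write_session_bids()]
#' @param dir Directory containing the files.
#' @param prefix File name prefix used at write time.
#' @return List with `signal`, `fs_hz`, `events`, `channels`,
#'   `truth_bursts`.
#' @export
read_session_bids <- function(dir, prefix = "session") {
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  meta <- jsonlite::read_json(p("_ieeg.json"), simplifyVector = TRUE)
  con <- file(p("_ieeg.bin"), "rb")
  x <- readBin(con, "numeric", n = length(meta$Channels) * meta$Samples,
               size = 4, endian = "little")
  close(con)
  sig <- matrix(x, nrow = length(meta$Channels))
  rownames(sig) <- meta$Channels
  attr(sig, "fs_hz") <- meta$SamplingFrequency
  list(signal = sig, fs_hz = meta$SamplingFrequency,
       events = read_tsv(p("_events.tsv")),
       channels = read_tsv(p("_channels.tsv")),
       truth_bursts = read_tsv(p("_truth_bursts.tsv")))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
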