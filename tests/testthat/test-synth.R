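test_that("schedule has the task's structure and invariants", {
  sch <- generate_schedule(20, seed = 3)
  expect_equal(nrow(sch$words), 240)
  expect_equal(nrow(sch$distractors), 20)
  expect_equal(nrow(sch$recalls), 20)
  expect_equal(unique(sch$words$duration_s), 1.6)
  expect_equal(unique(sch$distractors$duration_s), 20)
  expect_equal(unique(sch$recalls$duration_s), 30)
  for (l in 1:20) {
    w <- sch$words[sch$words$list_index == l, ]
    expect_equal(nrow(w), 12)
    gaps <- diff(w$onset_s) - 1.6  # inter-stimulus intervals
    expect_true(all(gaps >= 0.75 - 1e-9 & gaps <= 1.0 + 1e-9))
    d <- sch$distractors[l, ]
    expect_equal(d$onset_s, w$onset_s[12] + 1.6)  # immediately after word 12
    expect_equal(sch$recalls$onset_s[l], d$onset_s + 20)
  }
})

test_that("schedule is deterministic given a seed and rejects bad input", {
  expect_identical(generate_schedule(5, seed = 7), generate_schedule(5, seed = 7))
  expect_error(generate_schedule(0), "n_lists")
})

test_that("background noise has the configured spectral slope", {
  bg <- simulate_background(1, 60, 500, line_amp_uv = 0, seed = 11)
  p <- stats::spec.pgram(bg[1, ], plot = FALSE, taper = 0)
  f <- p$freq * 500
  keep <- f > 1 & f < 200
  slope <- coef(stats::lm(log(p$spec[keep]) ~ log(f[keep])))[2]
  expect_gt(slope, -2.4)
  expect_lt(slope, -1.6)
})

test_that("line-noise amplitude controls the 60 Hz spectral peak", {
  with_line <- simulate_background(1, 30, 500, line_amp_uv = 10, seed = 2)
  no_line <- simulate_background(1, 30, 500, line_amp_uv = 0, seed = 2)
  peak_power <- function(x) {
    p <- stats::spec.pgram(x, plot = FALSE, taper = 0)
    f <- p$freq * 500
    band <- f > 59 & f < 61
    max(p$spec[band]) / stats::median(p$spec[f > 50 & f < 70])
  }
  expect_gt(peak_power(with_line[1, ]), 100)
  expect_lt(peak_power(no_line[1, ]), 20)  # within the noise floor
})

test_that("background channels are mutually independent", {
  bg <- simulate_background(2, 60, 500, line_amp_uv = 0, seed = 1)
  # raw 1/f series have few effective dof, so whiten by differencing
  expect_lt(abs(cor(diff(bg[1, ]), diff(bg[2, ]))), 0.05)
  expect_lt(abs(cor(bg[1, ], bg[2, ])), 0.3)
  expect_error(simulate_background(1, 10, fs_hz = 600), "fs_hz")
})

test_that("burst injection respects rate zero and records exact truth", {
  sig <- matrix(0, 1, 5000)
  attr(sig, "fs_hz") <- 500
  win <- data.frame(onset_s = c(1, 5), duration_s = 3)
  spec0 <- burst_spec("HG", rate_hz = 0)
  out <- inject_bursts(sig, win, spec0, seed = 1)
  expect_equal(nrow(out$truth), 0)
  expect_identical(out$signal, sig)

  spec <- burst_spec("HG", rate_hz = 1)
  out <- inject_bursts(sig, win, spec, seed = 2)
  # every truth burst inside its window, inside band, nonzero signal there
  expect_true(all(out$truth$onset_s >= 1))
  expect_true(all(out$truth$peak_freq_hz >= 80 &
                    out$truth$peak_freq_hz <= 200))
  for (i in seq_len(nrow(out$truth))) {
    idx <- (round(out$truth$onset_s[i] * 500) + 5):(round(out$truth$offset_s[i] * 500) - 5)
    expect_gt(max(abs(out$signal[1, idx])), 0)
  }
})

test_that("poisson burst counts match the configured rate", {
  sig <- matrix(0, 1, 500 * 310)
  attr(sig, "fs_hz") <- 500
  win <- data.frame(onset_s = seq(0, 309, by = 3.1)[1:100], duration_s = 3)
  spec <- burst_spec("HG", rate_hz = 1, dur_mean_s = 0.1, dur_sd_s = 0.01)
  out <- inject_bursts(sig, win, spec, seed = 5)
  # 100 windows x 3 s x 1 Hz = 300 expected; 95% Poisson band
  expect_gt(nrow(out$truth), 300 - 1.96 * sqrt(300) - 5)
  expect_lt(nrow(out$truth), 300 + 1.96 * sqrt(300) + 5)
})

test_that("class multipliers scale per-class burst counts", {
  sig <- matrix(0, 1, 500 * 400)
  attr(sig, "fs_hz") <- 500
  win <- data.frame(onset_s = seq(0, 396, by = 4)[1:99], duration_s = 3,
                    label = rep(c(0, 1), length.out = 99))
  spec <- burst_spec("HG", rate_hz = 1, rate_mult = 3)
  out <- inject_bursts(sig, win, spec, seed = 8)
  cnt <- table(factor(win$label[match(out$truth$window_id,
                                      seq_len(nrow(win)))]))
  expect_gt(cnt["1"] / cnt["0"], 2)  # 3x rate, Poisson noise allowed
})

test_that("session labels follow recall_p and ground truth is consistent", {
  s0 <- simulate_session(n_lists = 2, n_channels = 1, recall_p = 0, seed = 4)
  expect_equal(sum(s0$recalled), 0)
  expect_equal(s0$recall_counts, c(0L, 0L))

  s <- simulate_session(n_lists = 20, n_channels = 1, recall_p = 0.25,
                        seed = 9)
  n_rec <- sum(s$recalled)
  expect_gt(n_rec, stats::qbinom(0.025, 240, 0.25) - 1)
  expect_lt(n_rec, stats::qbinom(0.975, 240, 0.25) + 1)
  expect_equal(sum(s$recall_counts), n_rec)
  expect_true(all(s$truth_bursts$offset_s <= ncol(s$signal) / s$fs_hz))
  # bit-reproducible
  s2 <- simulate_session(n_lists = 20, n_channels = 1, recall_p = 0.25,
                         seed = 9)
  expect_identical(s$signal, s2$signal)
  expect_identical(s$truth_bursts, s2$truth_bursts)
})

test_that("BIDS-style session layout round-trips", {
  s <- simulate_session(n_lists = 1, n_channels = 2, seed = 6)
  dir <- tempfile("bids")
  write_session_bids(s, dir)
  back <- read_session_bids(dir)
  expect_equal(back$fs_hz, s$fs_hz)
  expect_equal(dim(back$signal), dim(s$signal))
  # float32 round trip loses precision but not structure
  expect_lt(max(abs(back$signal - s$signal)), 1e-3)
  ev <- back$events
  expect_equal(sum(ev$trial_type == "WORD"), 12)
  expect_equal(sum(ev$trial_type == "DISTRACTOR"), 1)
  expect_equal(sum(ev$trial_type == "REC_START"), 1)
  expect_equal(sum(ev$recalled, na.rm = TRUE), sum(s$recalled))
  expect_equal(nrow(back$truth_bursts), nrow(s$truth_bursts))
  unlink(dir, recursive = TRUE)
})
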