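test_that("band-pass response matches the designed filter and the band", {
  fs <- 500
  taps <- design_bandpass(fs, 1, 12, transition = 1)
  # oracle: frequency response of the designed taps
  H <- function(f) abs(sum(taps * exp(-2i * pi * f / fs *
                                        (seq_along(taps) - 1))))
  t <- seq(0, 30, by = 1 / fs)[-1]
  rec <- eeg_recording(rbind(sin(2 * pi * 6 * t), sin(2 * pi * 50 * t)),
                       fs, c("A", "B"))
  out <- bandpass_filter(rec)$data
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  amp6 <- max(abs(out[1, mid]))
  amp50 <- max(abs(out[2, mid]))
  expect_equal(amp6, H(6), tolerance = 0.01)
  expect_lt(abs(amp6 - 1), 0.05)
  expect_equal(amp50, H(50), tolerance = 0.5)
  expect_lt(amp50, 0.01)
})

test_that("filtering a zero signal returns zero and invalid bands error", {
  rec <- eeg_recording(matrix(0, 2, 5000), 500, c("A", "B"))
  expect_equal(max(abs(bandpass_filter(rec)$data)), 0)
  expect_error(bandpass_filter(rec, 0, 12), "low")
  expect_error(bandpass_filter(rec, 12, 1), "low")
  expect_error(bandpass_filter(rec, 1, 300), "low")
  short <- eeg_recording(matrix(rnorm(200), 1), 500, "A")
  expect_error(bandpass_filter(short), "shorter than the filter")
})

test_that("band-pass is idempotent up to ripple on band-limited input", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)[-1]
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 9 * t)
  rec <- eeg_recording(rbind(x), fs, "A")
  once <- bandpass_filter(rec)
  twice <- bandpass_filter(once)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_gt(cor(once$data[1, mid], twice$data[1, mid]), 0.999)
})

test_that("a frontal-dominant source is identified and removed by ICA", {
  set.seed(31)
  fs <- 250
  n <- 6000
  t <- seq_len(n) / fs
  # blink: smoothed positive spikes
  blink <- rep(0, n)
  blink[seq(500, n, by = 900)] <- 1
  blink <- stats::filter(blink, dnorm(seq(-40, 40), sd = 12),
                         circular = TRUE)
  blink <- as.numeric(blink) / sd(blink)
  src <- rbind(blink, matrix(rnorm(5 * n), 5))
  mix <- matrix(runif(36, -1, 1), 6)
  mix[, 1] <- c(10, 9, 0.8, -0.5, 0.7, -0.9)  # frontal-dominant column
  labels <- c("Fp1", "Fp2", "C3", "C4", "P3", "P4")
  rec <- eeg_recording(mix %*% src, fs, labels)
  res <- remove_blink_components(rec, ratio_threshold = 3, seed = 1)
  expect_identical(res$n_rejected, 1L)
  v_before <- sum(apply(rec$data[1:2, ], 1, var))
  v_after <- sum(apply(res$recording$data[1:2, ], 1, var))
  expect_gt(1 - v_after / v_before, 0.8)
  expect_identical(dim(res$recording$data), dim(rec$data))
})

test_that("recordings without frontal sources pass through ICA unchanged", {
  set.seed(32)
  src <- matrix(rnorm(6 * 6000), 6)
  mix <- matrix(runif(36, 0.5, 1.5) * sample(c(-1, 1), 36, TRUE), 6)
  labels <- c("Fp1", "Fp2", "C3", "C4", "P3", "P4")
  rec <- eeg_recording(mix %*% src, 250, labels)
  res <- remove_blink_components(rec, ratio_threshold = 3, seed = 2)
  expect_identical(res$n_rejected, 0L)
  for (ch in 1:6)
    expect_gt(cor(rec$data[ch, ], res$recording$data[ch, ]), 0.99)
  # infinite threshold is the identity transform
  res_inf <- remove_blink_components(rec, ratio_threshold = Inf)
  expect_identical(res_inf$recording$data, rec$data)
  expect_identical(res_inf$n_rejected, 0L)
})

test_that("rank-deficient input is reported with its condition number", {
  x <- matrix(rnorm(3 * 1000), 3)
  x <- rbind(x, x[1, ])  # exactly collinear
  expect_error(fast_ica(x), "condition number")
})

test_that("epoching yields the printed sample count and drops edge events", {
  ev <- data.frame(onset_s = c(0.1, 2, 3, 4), stimulus_id = 1:4,
                   is_target = c(TRUE, FALSE, TRUE, FALSE),
                   character_index = 1L, run = 1L, block = 1:4)
  rec <- eeg_recording(matrix(rnorm(2 * 500 * 5), 2), 500, c("A", "B"),
                       events = ev)
  expect_warning(ep <- extract_epochs(rec), "dropped")
  expect_identical(attr(ep, "n_dropped"), 1L)
  expect_identical(dim(ep$data), c(3L, 2L, 500L))
  expect_identical(ep$time_ms[1], -200)
  expect_lt(max(ep$time_ms), 800)
  # epoch content matches the raw samples of the half-open window
  i0 <- round(2 * 500) + 1
  expect_equal(ep$data[1, , ], rec$data[, (i0 - 100):(i0 + 399)])
})

test_that("epoching conserves the scheduled event count on simulations", {
  fx <- make_fixture("tiny")
  ep <- extract_epochs(fx$recording)
  expect_identical(dim(ep$data)[1], nrow(fx$recording$events))
  expect_identical(attr(ep, "n_dropped"), 0L)
})

test_that("baseline z-scoring matches its definition and flags zero variance", {
  fs <- 250
  data <- array(rnorm(4 * 2 * 250), dim = c(4, 2, 250))
  ep <- fake_epochs(data, fs = fs)
  z <- zscore_baseline(ep)
  bi <- ep$time_ms >= -200 & ep$time_ms < 0
  for (tr in 1:4) for (ch in 1:2) {
    b <- data[tr, ch, bi]
    expect_equal(z$data[tr, ch, ], (data[tr, ch, ] - mean(b)) / sd(b),
                 tolerance = 1e-12)
    expect_equal(mean(z$data[tr, ch, bi]), 0, tolerance = 1e-12)
    expect_equal(sd(z$data[tr, ch, bi]), 1, tolerance = 1e-12)
  }
  # explicit value: baseline mean 2 sd 3, response sample 8 -> 2.0
  x <- array(0, dim = c(1, 1, 250))
  b <- rnorm(50)
  x[1, 1, 1:50] <- 2 + 3 * (b - mean(b)) / sd(b)
  x[1, 1, 100] <- 8
  z2 <- zscore_baseline(fake_epochs(x, fs = fs))
  expect_equal(z2$data[1, 1, 100], 2, tolerance = 1e-12)

  const <- fake_epochs(array(5, dim = c(1, 1, 250)), fs = fs)
  expect_error(zscore_baseline(const), "zero baseline variance")
})
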