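test_that("notch removes mains tone and band-pass preserves gamma", {
  fs <- 2048
  x50 <- tone(50, fs, dur_s = 4)
  y50 <- bandpass_notch(x50, fs)
  expect_lt(mid_rms(y50) / mid_rms(x50), 0.01)

  x40 <- tone(40, fs, dur_s = 4)
  y40 <- bandpass_notch(x40, fs)
  expect_lt(abs(mid_rms(y40) / mid_rms(x40) - 1), 0.05)

  expect_equal(bandpass_notch(numeric(4096), fs), numeric(4096))
  expect_length(y50, length(x50))
})

test_that("pass-band filtering is idempotent within tolerance", {
  y1 <- bandpass_notch(tone(40, dur_s = 4), 2048)
  y2 <- bandpass_notch(y1, 2048)
  expect_lt(abs(mid_rms(y2) / mid_rms(y1) - 1), 0.05)
})

test_that("filtering rejects band edges beyond Nyquist", {
  cfg <- preprocess_config(bandpass_hz = c(1, 600))
  expect_error(bandpass_notch(rnorm(4096), 1000, cfg), "Nyquist")
})

test_that("the chain preserves the dominant bin of a pass-band tone", {
  fs <- 2048
  rec <- eeg_recording(tone(40, fs, 6, amp = 5), fs)
  out <- preprocess_recording(rec, onsets = 2, duration_s = 2,
                              condition = "motor", hand = "right")
  psd <- psd_multitaper(out$trials$trials[[1]], fs)
  expect_equal(psd$freqs[which.max(psd$power)], 40, tolerance = 1e-9)
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- seq_len(500)
  expect_lt(max(abs(detrend_linear(2 * t + 3))), 1e-9)
  expect_equal(detrend_linear(rep(7, 100)), numeric(100))

  set.seed(11)
  w <- rnorm(2000)
  d <- detrend_linear(w)
  tt <- seq_along(d) - mean(seq_along(d))
  expect_lt(abs(sum(tt * d) / sum(tt^2)), 1e-12)   # zero slope
  expect_lt(abs(mean(d)), 1e-12)
  expect_equal(var(d), var(w), tolerance = 0.01)
  expect_error(detrend_linear(1), "at least 2")
})

test_that("artifact rejection flags spikes and leaves kept trials untouched", {
  set.seed(5)
  trials <- replicate(10, rnorm(1024, sd = 5), simplify = FALSE)
  trials[[4]][300] <- 500
  ts <- trial_set(trials, fs = 512, "motor", "right", 2)
  res <- reject_artifacts(ts, preprocess_config(artifact_amplitude_uV = 100))
  expect_identical(res$rejected_indices, 4L)
  expect_identical(res$trials$trials, trials[-4])

  # identical sub-threshold trials: nothing rejected
  same <- trial_set(replicate(5, tone(10, 512, 2), simplify = FALSE),
                    512, "motor", "left", 2)
  expect_length(reject_artifacts(same)$rejected_indices, 0L)

  expect_error(
    reject_artifacts(ts, preprocess_config(artifact_amplitude_uV = 0.001)),
    "no clean trials")
})

test_that("jump detection catches steps that stay under the amplitude cap", {
  set.seed(6)
  trials <- replicate(8, rnorm(1024, sd = 5), simplify = FALSE)
  trials[[2]][500:1024] <- trials[[2]][500:1024] + 80  # step, peak < 100
  ts <- trial_set(trials, fs = 512, "motor", "right", 2)
  res <- reject_artifacts(ts, preprocess_config())
  expect_identical(res$rejected_indices, 2L)
})

test_that("preprocess_config validates its bands and thresholds", {
  expect_error(preprocess_config(bandpass_hz = c(100, 1)), "low < high")
  expect_error(preprocess_config(artifact_zmax = 0), "positive")
})
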