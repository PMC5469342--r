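test_that("DPSS tapers are orthonormal and match independent references", {
  v <- dpss_tapers(64, 4, 3)
  expect_equal(crossprod(v), diag(3), tolerance = 1e-10)
  # frozen reference values (scipy.signal.windows.dpss); tapers are
  # defined up to sign, so align each column before comparing
  ref <- rbind(c(3.10637000e-05, -2.47111500e-04, 1.34658050e-03),
               c(4.64840827e-02, -1.24930293e-01, 1.97670249e-01),
               c(2.47337187e-01, -1.87094275e-02, -1.67874118e-01))
  got <- v[c(1, 16, 32), ]
  for (j in 1:3) got[, j] <- got[, j] * sign(sum(got[, j] * ref[, j]))
  expect_equal(got, ref, tolerance = 1e-7)
})

test_that("multitaper PSD of white noise integrates to its variance", {
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    w <- rnorm(4096)
    p <- psd_multitaper(w, 2048)
    df <- p$freqs[2] - p$freqs[1]
    sum(p$power) * df / var(w)
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.05)
  # across trial lengths too
  for (dur in c(1, 2, 4)) {
    set.seed(100 + dur)
    w <- rnorm(2048 * dur)
    p <- psd_multitaper(w, 2048)
    expect_equal(sum(p$power) * (p$freqs[2] - p$freqs[1]) / var(w), 1,
                 tolerance = 0.05)
  }
})

test_that("a tone of amplitude A carries band-integrated power A^2/2", {
  for (A in c(1, 2)) {
    p <- psd_multitaper(tone(40, amp = A), 2048)
    df <- p$freqs[2] - p$freqs[1]
    got <- sum(p$power[p$freqs >= 35 & p$freqs <= 45]) * df
    expect_equal(got, A^2 / 2, tolerance = 0.02 * A^2)
  }
  expect_equal(psd_multitaper(numeric(4096), 2048)$power,
               numeric(2049))
})

test_that("the default smoothing gives 7 tapers on 2-s trials", {
  p <- psd_multitaper(rnorm(4096), 2048, smoothing_hz = 2)
  expect_identical(p$n_tapers, 7L)
  # very short trial falls back to a single Hann taper
  p2 <- psd_multitaper(rnorm(600), 2048, smoothing_hz = 2)
  expect_identical(p2$n_tapers, 1L)
})

test_that("band_power averages closed-interval bins", {
  p <- structure(list(freqs = seq(0, 100, by = 1), power = rep(3, 101),
                      fs = 200, n_tapers = 1L), class = "psd_estimate")
  expect_equal(band_power(p, c(30, 60)), 3)
  # closed interval: endpoints included
  p$power <- as.numeric(p$freqs %in% c(30, 60))
  expect_equal(band_power(p, c(30, 60)), 2 / 31)
  # out-of-band power contributes nothing
  p$power <- as.numeric(p$freqs == 70)
  expect_equal(band_power(p, c(30, 60)), 0)
  # linear ramp: mean equals the midpoint value
  p$power <- 2 * p$freqs
  expect_equal(band_power(p, c(30, 60)), 90)
  expect_error(band_power(p, c(101, 110)), "no frequency bins")
})

test_that("gba_per_trial routes through IMFs and excludes missing modes", {
  fs <- 2048
  trials <- trial_set(replicate(3, tone(40, fs, 2), simplify = FALSE),
                      fs, "motor", "right", 2)
  orig <- gba_per_trial(trials, "original")
  via1 <- gba_per_trial(trials, "imf1")
  expect_equal(via1$value_uV2, orig$value_uV2, tolerance = 0.1)

  # a 5 Hz tone has no gamma-band content in IMF1
  lowt <- trial_set(replicate(2, tone(5, fs, 2), simplify = FALSE),
                    fs, "motor", "left", 2)
  low1 <- gba_per_trial(lowt, "imf1")
  total <- 0.5 / 30    # tone power spread as mean density over the band
  expect_lt(max(low1$value_uV2), 0.01 * total)

  expect_error(gba_per_trial(trial_set(list(), fs, "motor", "right", 2),
                             "original"), "empty")
})

test_that("band power scales quadratically with signal gain", {
  set.seed(9)
  x <- rnorm(4096) + tone(45)
  ts1 <- trial_set(list(x), 2048, "motor", "right", 2)
  ts3 <- trial_set(list(3 * x), 2048, "motor", "right", 2)
  g1 <- gba_per_trial(ts1, "original")$value_uV2
  g3 <- gba_per_trial(ts3, "original")$value_uV2
  expect_equal(g3 / g1, 9, tolerance = 1e-9)
})

test_that("IMF1 filtering raises the burst-to-background band ratio", {
  # mechanism behind the headline effect, at single-trial scale:
  # gamma burst + 1/f-ish background, IMF1 sheds low-frequency power
  set.seed(21)
  fs <- 2048
  bg <- bandpass_notch(10 * rnorm(4096), fs)
  burst <- tone(45, fs, 2) * (0.5 - 0.5 * cos(2 * pi * (0:4095) / 4095))
  with_b <- trial_set(list(bg + 2 * burst), fs, "motor", "right", 2)
  no_b <- trial_set(list(bg), fs, "basal", "none", 2)
  ratio <- function(ts)
    gba_per_trial(ts, "imf1")$value_uV2 /
    gba_per_trial(ts, "original")$value_uV2
  expect_gt(ratio(with_b), ratio(no_b))
})
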