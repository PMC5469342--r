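test_that("find_extrema matches direct inspection and a brute-force scan", {
  ex <- find_extrema(c(0, 1, 0, -1, 0))
  expect_identical(ex, list(maxima = 2L, minima = 4L))

  expect_identical(find_extrema(seq_len(50)),
                   list(maxima = integer(0), minima = integer(0)))

  # one period of a sine at 64 samples: brute-force interior scan agrees
  x <- sin(2 * pi * (0:63) / 64)
  brute_max <- which(vapply(2:63, function(i)
    x[i] > x[i - 1] && x[i] > x[i + 1], logical(1))) + 1L
  brute_min <- which(vapply(2:63, function(i)
    x[i] < x[i - 1] && x[i] < x[i + 1], logical(1))) + 1L
  ex <- find_extrema(x)
  expect_identical(ex$maxima, brute_max)
  expect_identical(ex$minima, brute_min)
  expect_length(ex$maxima, 1L)
  expect_length(ex$minima, 1L)
})

test_that("plateau extrema report the plateau midpoint", {
  x <- c(0, 1, 2, 2, 2, 1, 0, -1, -1, 0)
  ex <- find_extrema(x)
  expect_identical(ex$maxima, 4L)   # plateau 3..5
  expect_identical(ex$minima, 8L)   # plateau 8..9 -> midpoint 8
})

test_that("envelopes interpolate extrema and degenerate gracefully", {
  # collinear knots give a constant envelope
  x <- rep(c(2, 0), 10)
  env <- emd_envelope(x, which(x == 2))
  expect_equal(env, rep(2, 20), tolerance = 1e-12)

  # upper envelope of a long sinusoid sits near the amplitude
  s <- tone(8, fs = 512, dur_s = 2)       # 16 periods
  ex <- find_extrema(s)
  ue <- emd_envelope(s, ex$maxima)
  interior <- 65:(length(s) - 64)
  expect_true(all(abs(ue[interior] - 1) < 0.02))
  expect_true(all(ue[ex$maxima] >= s[ex$maxima] - 1e-12))

  # two extrema, no extension: a straight line between them
  y <- c(0, 3, 2, 1, 5, 0)
  env2 <- emd_envelope(y, c(2L, 5L), boundary = "none")
  expect_equal(env2[2:5], seq(3, 5, length.out = 4))

  expect_error(emd_envelope(seq_len(10), integer(0)), "monotone")
})

test_that("is_imf accepts oscillatory zero-mean modes and rejects offsets", {
  s <- tone(10, fs = 512, dur_s = 2)     # integer periods
  expect_true(is_imf(s))
  expect_false(is_imf(s + 5))            # no zero crossings
  expect_false(is_imf(rep(1, 100)))      # constant: no extrema
})

test_that("EMD separates a two-tone mixture into its components", {
  fs <- 2048
  t <- (0:4095) / fs
  hi <- sin(2 * pi * 40 * t)
  lo <- sin(2 * pi * 4 * t)
  d <- emd(hi + lo, fs = fs)
  expect_gte(d$n_imfs, 2L)
  expect_gt(cor(d$imfs[[1]], hi), 0.95)
  expect_gt(cor(d$imfs[[2]], lo), 0.95)
  expect_lt(reconstruction_rel_error(d, hi + lo), 1e-8)
})

test_that("constant input yields no IMFs and the input as residue", {
  x <- rep(3.5, 100)
  d <- emd(x)
  expect_identical(d$n_imfs, 0L)
  expect_identical(d$residue, x)
})

test_that("reconstruction and IMF validity hold across random mixtures", {
  for (seed in 1:25) {
    x <- random_emd_signal(seed)
    d <- emd(x, fs = 2048)
    expect_lt(reconstruction_rel_error(d, x), 1e-8)
    expect_lte(d$n_imfs, 5L)
    for (im in d$imfs) expect_true(imf_counts_ok(im))
  }
})

test_that("IMF mean frequencies decrease with mode index", {
  set.seed(42)
  x <- rnorm(4096, sd = 2) + tone(45) + tone(10, amp = 3)
  d <- emd(x, fs = 2048)
  mf <- vapply(d$imfs, mean_frequency, numeric(1), fs = 2048)
  expect_true(all(diff(mf) < 0))
})

test_that("mean_frequency locates tones and orders bandwidths", {
  expect_equal(mean_frequency(tone(40), 2048), 40, tolerance = 1)
  # broader-band noise has higher mean frequency than low-passed noise
  set.seed(3)
  w <- rnorm(8192)
  lp100 <- bandpass_notch(w, 2048, preprocess_config(bandpass_hz = c(1, 100)))
  lp50 <- bandpass_notch(w, 2048, preprocess_config(bandpass_hz = c(1, 50)))
  expect_gt(mean_frequency(lp100, 2048), mean_frequency(lp50, 2048))
  # DC offset is excluded
  expect_equal(mean_frequency(10 + 0.01 * tone(40), 2048), 40,
               tolerance = 1)
  expect_error(mean_frequency(rep(1, 100), 2048), "degenerate")
})

test_that("the sampling-rate contract warns below 5x the band of interest", {
  expect_warning(check_emd_sampling(200, 60), "5x")
  expect_silent(check_emd_sampling(2048, 60))
})

test_that("emd rejects non-finite input", {
  expect_error(emd(c(rnorm(100), NA)), "finite")
})
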