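test_that("spec validation enforces the sampling and ERS bounds", {
  expect_error(synth_subject_spec(fs = 150, gamma_freq_hz = 40), "5x")
  expect_error(synth_subject_spec(ers_true_percent = -100), "-100")
  expect_error(synth_subject_spec(artifact_rate = 2), "probability")
})

test_that("the same seed reproduces a subject bit for bit", {
  sp <- synth_subject_spec(n_trials_per_hand = 3L, basal_minutes = 0.1,
                           seed = 77L)
  a <- make_subject(sp)
  b <- make_subject(sp)
  expect_identical(a$basal$samples, b$basal$samples)
  expect_identical(a$motor$samples, b$motor$samples)
  expect_identical(a$onsets, b$onsets)
})

test_that("generated gamma power ratio matches the requested ERS", {
  # noise-free oracle: band-integrated periodogram of the gamma component
  sp <- synth_subject_spec(n_trials_per_hand = 5L, basal_minutes = 1 / 6,
                           background_sigma_uV = 0,
                           rhythm_components = list(),
                           ers_true_percent = 100, seed = 3L)
  s <- make_subject(sp)
  bp <- function(x) {
    p <- Mod(fft(x))^2 / length(x)
    f <- (seq_along(x) - 1) * sp$fs / length(x)
    sum(p[f >= 30 & f <= 60]) / length(x)
  }
  n <- sp$trial_s * sp$fs
  pb <- mean(vapply(seq_len(5), function(k)
    bp(s$basal$samples[((k - 1) * n + 1):(k * n)]), numeric(1)))
  pm <- mean(vapply(seq_len(5), function(k)
    bp(s$motor$samples[((k - 1) * n + 1):(k * n)]), numeric(1)))
  expect_equal(pm / pb, 2, tolerance = 0.01)
  # noise-free pipeline recovery of a 100% effect
  ers <- cohort_subject_ers(s, "original")
  expect_equal(unname(ers), 100, tolerance = 5)
})

test_that("motor recordings carry correct cue annotations per hand", {
  sp <- synth_subject_spec(n_trials_per_hand = 4L, basal_minutes = 0.1)
  s <- make_subject(sp)
  expect_equal(nrow(s$onsets), 8)
  expect_equal(sum(s$onsets$label == "cue_right"), 4)
  expect_equal(length(s$motor$samples), 8 * sp$trial_s * sp$fs)
  expect_equal(diff(s$onsets$onset), rep(sp$trial_s, 7))
})

test_that("artifact trials receive detectable spikes", {
  sp <- synth_subject_spec(n_trials_per_hand = 10L, basal_minutes = 0.1,
                           artifact_rate = 0.5, seed = 9L)
  s <- make_subject(sp)
  expect_gt(max(abs(s$motor$samples)), 400)
})

test_that("cohorts share or vary true ERS as configured, reproducibly", {
  tmpl <- synth_subject_spec(n_trials_per_hand = 2L, basal_minutes = 0.1,
                             ers_true_percent = 30)
  same <- make_cohort(3, tmpl, between_subject_sd = 0, seed = 5L)
  expect_equal(vapply(same, function(b) b$spec$ers_true_percent, numeric(1)),
               rep(30, 3))
  again <- make_cohort(3, tmpl, between_subject_sd = 0, seed = 5L)
  expect_identical(same[[2]]$motor$samples, again[[2]]$motor$samples)

  # drawn effect sizes scatter around the template mean
  co <- make_cohort(25, tmpl, between_subject_sd = 20, seed = 11L)
  got <- vapply(co, function(b) b$spec$ers_true_percent, numeric(1))
  expect_equal(mean(got), 30, tolerance = 3 * 20 / sqrt(25))
  expect_gt(sd(got), 10)
})

test_that("background band power is stationary across conditions", {
  # with the gamma component switched off, basal and motor 30-60 Hz
  # power differ only by sampling error across seeds
  diffs <- vapply(1:8, function(s) {
    sp <- synth_subject_spec(n_trials_per_hand = 5L, basal_minutes = 1 / 6,
                             gamma_basal_amp_uV = 0, ers_true_percent = 0,
                             seed = s)
    b <- make_subject(sp)
    basal <- epoch_basal(b$basal, 2)
    onr <- b$onsets$onset[b$onsets$label == "cue_right"]
    motor <- epoch(b$motor, onr, 2, "motor", "right")
    mean(gba_per_trial(motor, "original")$value_uV2) -
      mean(gba_per_trial(basal, "original")$value_uV2)
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.05)
})
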