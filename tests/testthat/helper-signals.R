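# Signal fixtures shared across tests. Everything is generated in code;
# seeds are fixed where randomness is involved.

tone <- function(freq_hz, fs = 2048, dur_s = 2, amp = 1, phase = 0) {
  t <- (seq_len(round(fs * dur_s)) - 1) / fs
  amp * sin(2 * pi * freq_hz * t + phase)
}

# steady-state RMS: middle half of the series, away from filter edges
mid_rms <- function(x) {
  n <- length(x)
  i <- (n %/% 4):(3 * n %/% 4)
  sqrt(mean(x[i]^2))
}

# mixed fixture family used by the decomposition invariance tests
random_emd_signal <- function(seed, fs = 2048, dur_s = 2) {
  set.seed(seed)
  n <- round(fs * dur_s)
  kind <- seed %% 3
  if (kind == 0) {
    stats::rnorm(n)
  } else if (kind == 1) {
    tone(sample(25:60, 1), fs, dur_s) +
      tone(sample(3:8, 1), fs, dur_s, amp = runif(1, 0.5, 2))
  } else {
    stats::rnorm(n, sd = 0.5) + tone(sample(30:50, 1), fs, dur_s) +
      tone(sample(4:10, 1), fs, dur_s)
  }
}

# interior IMF-criterion check: extrema vs zero crossings with the two
# boundary samples at each end excluded
imf_counts_ok <- function(imf, tol = 1L) {
  n <- length(imf)
  core <- imf[3:(n - 2)]
  ex <- find_extrema(core)
  n_ext <- length(ex$maxima) + length(ex$minima)
  s <- sign(core)
  s <- s[s != 0]
  n_zc <- sum(s[-length(s)] != s[-1])
  abs(n_ext - n_zc) <= tol
}

reconstruction_rel_error <- function(dec, x) {
  recon <- dec$residue
  for (im in dec$imfs) recon <- recon + im
  max(abs(recon - x)) / max(abs(x), .Machine$double.eps)
}

# scaled-down cohort templates: 20 trials/hand and 1 min of basal
# recording instead of the emulated experiment's 100 and 18 min
recovery_template <- function(ers_true = 50) {
  synth_subject_spec(n_trials_per_hand = 20L, basal_minutes = 1,
                     background_sigma_uV = 1, gamma_basal_amp_uV = 2.5,
                     gamma_freq_hz = 40, ers_true_percent = ers_true)
}

headline_template <- function() {
  synth_subject_spec(n_trials_per_hand = 20L, basal_minutes = 1,
                     background_sigma_uV = 10, gamma_basal_amp_uV = 2,
                     gamma_freq_hz = 45, ers_true_percent = 100)
}

# subject-level ERS for one hand and several methods, bypassing file I/O
cohort_subject_ers <- function(bundle, methods, hand = "right") {
  pp <- preprocess_config()
  basal <- preprocess_recording(bundle$basal, NULL, bundle$spec$trial_s,
                                "basal", "none", pp)
  on_h <- bundle$onsets$onset[bundle$onsets$label == paste0("cue_", hand)]
  motor <- preprocess_recording(bundle$motor, on_h, bundle$spec$trial_s,
                                "motor", hand, pp)
  vapply(methods, function(m) {
    gb <- gba_per_trial(basal$trials, m)
    gm <- gba_per_trial(motor$trials, m)
    subject_ers(gb, gm, m, hand)$ers_percent
  }, numeric(1))
}
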