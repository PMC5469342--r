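# Synthetic single-channel EEG with known ground-truth gamma ERS.
#
# Each recording is 1/f-shaped broadband background noise plus fixed
# alpha/beta rhythm sinusoids plus a narrowband gamma component injected
# per trial as a Hann-windowed burst with a fresh random phase (induced,
# non-phase-locked activity). Basal pseudo-trials carry the same kind of
# burst at spontaneous power; motor trials carry it scaled so that the
# gamma-component power ratio motor/basal equals
# 1 + ers_true_percent/100 exactly. Using the same burst waveform class
# in both conditions means any quadratic spectral estimator weights the
# two conditions identically, so the power ratio is the ground truth for
# the estimated ERS, not just for the generator.

#' Specification of one synthetic subject
#'
#' Defaults mirror the emulated experiment: 2048 Hz sampling, 2-s trials,
#' 100 motor trials per hand, 18 min of basal recording. Tests and the
#' acceptance checks pass scaled-down sizes explicitly.
#'
#' @param fs Sampling frequency in Hz; must be at least `5 *
#'   gamma_freq_hz` (the EMD band-separation condition).
#' @param trial_s Trial duration in seconds.
#' @param n_trials_per_hand Motor trials per hand.
#' @param basal_minutes Basal recording length in minutes.
#' @param background_sigma_uV Time-domain standard deviation of the 1/f
#'   background (microvolts), band-limited to 1-100 Hz.
#' @param rhythm_components List of `c(freq_hz, amplitude_uV)` sinusoids
#'   (defaults: 10 Hz alpha at 5 uV, 20 Hz beta at 2 uV).
#' @param gamma_freq_hz Frequency of the gamma component in Hz.
#' @param gamma_basal_amp_uV Equivalent continuous-tone amplitude of the
#'   basal (spontaneous) gamma component in microvolts: the per-trial
#'   basal gamma burst carries mean-square power
#'   `gamma_basal_amp_uV^2 / 2`.
#' @param ers_true_percent Ground-truth ERS: the gamma-component power in
#'   motor trials is `(1 + ers_true_percent/100)` times the basal gamma
#'   power. Must exceed -100.
#' @param artifact_rate Per-trial probability of a 500 uV spike artifact.
#' @param seed Integer RNG seed; the same spec yields bit-identical data.
#' @return A `synth_subject_spec` list.
#' @export
synth_subject_spec <- function(fs = 2048, trial_s = 2,
                               n_trials_per_hand = 100L,
                               basal_minutes = 18,
                               background_sigma_uV = 10,
                               rhythm_components = list(c(10, 5), c(20, 2)),
                               gamma_freq_hz = 40,
                               gamma_basal_amp_uV = 1,
                               ers_true_percent = 50,
                               artifact_rate = 0,
                               seed = 1L) {
  if (ers_true_percent <= -100)
    stop("ers_true_percent must exceed -100", call. = FALSE)
  if (fs < 5 * gamma_freq_hz)
    stop("fs must be at least 5x gamma_freq_hz (EMD sampling condition)",
         call. = FALSE)
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must be a probability", call. = FALSE)
  structure(list(fs = fs, trial_s = trial_s,
                 n_trials_per_hand = as.integer(n_trials_per_hand),
                 basal_minutes = basal_minutes,
                 background_sigma_uV = background_sigma_uV,
                 rhythm_components = rhythm_components,
                 gamma_freq_hz = gamma_freq_hz,
                 gamma_basal_amp_uV = gamma_basal_amp_uV,
                 ers_true_percent = ers_true_percent,
                 artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "synth_subject_spec")
}

# 1/f-power-shaped Gaussian noise, band-limited to [f_lo, f_hi] Hz,
# scaled to standard deviation sigma. Generated by spectral shaping of
# white noise, so it is stationary across the whole trace.
one_over_f_noise <- function(n, fs, sigma, f_lo = 1, f_hi = 100) {
  if (sigma == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  amp <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(pmax(f, f_lo)), 0)
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  x * (sigma / stats::sd(x))
}

# per-trial gamma component: a Hann-windowed burst with random phase,
# scaled so its mean-square over the trial equals `power`.
gamma_trial <- function(n, fs, freq, power) {
  phase <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  carrier <- sin(2 * pi * freq * t + phase)
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  g <- env * carrier
  ms <- mean(g^2)
  if (ms == 0 || power == 0) return(numeric(n))
  g * sqrt(power / ms)
}

# one condition trace built trial-by-trial
build_trace <- function(n_trials, spec, gamma_power) {
  n <- round(spec$trial_s * spec$fs)
  total <- n_trials * n
  x <- one_over_f_noise(total, spec$fs, spec$background_sigma_uV)
  t <- (seq_len(total) - 1) / spec$fs
  for (rc in spec$rhythm_components)
    x <- x + rc[2] * sin(2 * pi * rc[1] * t + stats::runif(1, 0, 2 * pi))
  for (k in seq_len(n_trials)) {
    idx <- ((k - 1L) * n + 1L):(k * n)
    x[idx] <- x[idx] + gamma_trial(n, spec$fs, spec$gamma_freq_hz,
                                   gamma_power)
    if (spec$artifact_rate > 0 &&
        stats::runif(1) < spec$artifact_rate) {
      x[idx[sample.int(n, 1)]] <- 500
    }
  }
  x
}

#' Generate one synthetic subject
#'
#' Builds a basal recording (consecutive pseudo-trials with spontaneous
#' gamma bursts) and a motor recording (right-hand trials followed by
#' left-hand trials with stronger induced bursts), with cue annotations. The
#' gamma-component power ratio motor/basal equals
#' `1 + ers_true_percent/100` exactly by construction; everything is
#' reproducible from `spec$seed`.
#'
#' @param spec A [synth_subject_spec()].
#' @return List with `basal` ([eeg_recording()]), `motor`
#'   ([eeg_recording()] with `cue_right`/`cue_left` annotations),
#'   `onsets` (data frame `onset`, `label`) and `spec`.
#' @export
make_subject <- function(spec) {
  stopifnot(inherits(spec, "synth_subject_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- round(spec$trial_s * spec$fs)
  p_basal <- spec$gamma_basal_amp_uV^2 / 2
  p_motor <- p_basal * (1 + spec$ers_true_percent / 100)

  n_basal <- max(1L, floor(spec$basal_minutes * 60 / spec$trial_s))
  basal <- build_trace(n_basal, spec, p_basal)

  n_mot <- 2L * spec$n_trials_per_hand
  motor <- build_trace(n_mot, spec, p_motor)
  onset <- (seq_len(n_mot) - 1L) * spec$trial_s
  label <- rep(c("cue_right", "cue_left"), each = spec$n_trials_per_hand)
  onsets <- data.frame(onset = onset, label = label,
                       stringsAsFactors = FALSE)

  list(basal = eeg_recording(basal, spec$fs, "Cz"),
       motor = eeg_recording(motor, spec$fs, "Cz", onsets),
       onsets = onsets, spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort
#'
#' Draws each subject's true ERS from
#' `Normal(template ers_true_percent, between_subject_sd)`, truncated
#' above -100, and derives per-subject seeds deterministically from the
#' master seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param spec_template A [synth_subject_spec()] used for every subject
#'   (its `ers_true_percent` is the cohort mean).
#' @param between_subject_sd Between-subject standard deviation of true
#'   ERS in percent.
#' @param seed Master seed.
#' @return List of subject bundles as returned by [make_subject()], with
#'   `subject_id` added.
#' @export
make_cohort <- function(n_subjects, spec_template = synth_subject_spec(),
                        between_subject_sd = 20, seed = 1L) {
  stopifnot(n_subjects >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ers <- stats::rnorm(n_subjects, spec_template$ers_true_percent,
                      between_subject_sd)
  ers <- pmax(ers, -99.9)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    sp <- spec_template
    sp$ers_true_percent <- ers[i]
    sp$seed <- sub_seeds[i]
    b <- make_subject(sp)
    b$subject_id <- sprintf("S%02d", i)
    b
  })
}
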