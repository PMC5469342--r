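#' Pre-processing configuration
#'
#' Settings for the cleaning chain applied before spectral analysis:
#' zero-phase band-pass (default 1-100 Hz) and mains notch (default
#' 49-51 Hz, i.e. 50 Hz mains; set `notch_hz = c(59, 61)` for 60 Hz
#' regions), per-trial linear detrending, and automatic artifact
#' rejection by peak amplitude and first-difference jump score.
#'
#' Filters are Butterworth IIR applied forward-backward (`filtfilt`), so
#' the chain introduces no group delay and trial timing relative to the
#' cue is undistorted. The band-pass is realized as a high-pass/low-pass
#' cascade (default order 4 each); the notch is a band-stop (default
#' order 2 per pass).
#'
#' @param bandpass_hz Length-2 numeric, pass band in Hz.
#' @param notch_hz Length-2 numeric, stop band in Hz.
#' @param artifact_amplitude_uV Reject a trial whose peak absolute
#'   amplitude exceeds this (microvolts).
#' @param artifact_zmax Reject a trial whose largest absolute
#'   first-difference robust z-score (median/MAD over all trials' sample
#'   differences) exceeds this.
#' @param detrend Remove the per-trial least-squares linear trend.
#' @param bp_order Order of each band-pass half (high-pass and low-pass).
#' @param notch_order Order of the band-stop filter.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(bandpass_hz = c(1, 100),
                              notch_hz = c(49, 51),
                              artifact_amplitude_uV = 100,
                              artifact_zmax = 8,
                              detrend = TRUE,
                              bp_order = 4L,
                              notch_order = 2L) {
  stopifnot(length(bandpass_hz) == 2, length(notch_hz) == 2)
  if (!(0 < bandpass_hz[1] && bandpass_hz[1] < bandpass_hz[2]))
    stop("bandpass_hz must satisfy 0 < low < high", call. = FALSE)
  if (!(0 < notch_hz[1] && notch_hz[1] < notch_hz[2]))
    stop("notch_hz must satisfy 0 < low < high", call. = FALSE)
  if (artifact_amplitude_uV <= 0 || artifact_zmax <= 0)
    stop("artifact thresholds must be strictly positive", call. = FALSE)
  structure(list(bandpass_hz = as.numeric(bandpass_hz),
                 notch_hz = as.numeric(notch_hz),
                 artifact_amplitude_uV = artifact_amplitude_uV,
                 artifact_zmax = artifact_zmax,
                 detrend = isTRUE(detrend),
                 bp_order = as.integer(bp_order),
                 notch_order = as.integer(notch_order)),
            class = "preprocess_config")
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies the configured Butterworth band-pass (as a high-pass then
#' low-pass cascade) followed by the mains band-stop, each
#' forward-backward so the net phase response is zero and output length
#' equals input length.
#'
#' @param samples Numeric voltage series (microvolts).
#' @param fs Sampling frequency in Hz.
#' @param cfg A [preprocess_config()].
#' @return Filtered series, same length as the input.
#' @export
bandpass_notch <- function(samples, fs, cfg = preprocess_config()) {
  nyq <- fs / 2
  if (cfg$bandpass_hz[2] >= nyq || cfg$notch_hz[2] >= nyq)
    stop("filter band edges must lie below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  x <- as.numeric(samples)
  hp <- signal::butter(cfg$bp_order, cfg$bandpass_hz[1] / nyq, type = "high")
  lp <- signal::butter(cfg$bp_order, cfg$bandpass_hz[2] / nyq, type = "low")
  bs <- signal::butter(cfg$notch_order, cfg$notch_hz / nyq, type = "stop")
  x <- signal::filtfilt(hp, x)
  x <- signal::filtfilt(lp, x)
  x <- signal::filtfilt(bs, x)
  as.numeric(x)
}

#' Remove the least-squares linear trend
#'
#' Subtracts the ordinary least-squares line fitted to the series, so the
#' output has zero mean and zero regression slope.
#'
#' @param samples Numeric series, length >= 2.
#' @return Detrended series.
#' @export
detrend_linear <- function(samples) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to detrend", call. = FALSE)
  t <- seq_len(n) - (n + 1) / 2           # centered time axis
  beta <- sum(t * samples) / sum(t * t)
  samples - mean(samples) - beta * t
}

#' Automatic artifact rejection
#'
#' Deterministic surrogate for visual trial inspection: a trial is
#' rejected if its peak absolute amplitude exceeds
#' `artifact_amplitude_uV`, or if any of its first differences has a
#' robust z-score (relative to the median and MAD of the sample-to-sample
#' differences pooled over all trials) exceeding `artifact_zmax` in
#' absolute value. Kept trials are returned unchanged and in order.
#'
#' @param trials A [trial_set()].
#' @param cfg A [preprocess_config()].
#' @return List with `trials` (the cleaned [trial_set()]) and
#'   `rejected_indices` (1-based indices into the input). Errors if every
#'   trial is rejected.
#' @export
reject_artifacts <- function(trials, cfg = preprocess_config()) {
  stopifnot(inherits(trials, "trial_set"))
  if (length(trials$trials) == 0L)
    stop("empty trial set", call. = FALSE)
  diffs <- lapply(trials$trials, diff)
  all_d <- unlist(diffs, use.names = FALSE)
  med <- stats::median(all_d)
  s <- stats::mad(all_d)
  if (s == 0) s <- Inf  # constant trials: jump score cannot fire
  bad <- vapply(seq_along(trials$trials), function(i) {
    max(abs(trials$trials[[i]])) > cfg$artifact_amplitude_uV ||
      max(abs(diffs[[i]] - med)) / s > cfg$artifact_zmax
  }, logical(1))
  if (all(bad))
    stop("no clean trials: every trial exceeded the artifact thresholds",
         call. = FALSE)
  kept <- trial_set(trials$trials[!bad], trials$fs, trials$condition,
                    trials$hand, trials$trial_duration_s)
  list(trials = kept, rejected_indices = which(bad))
}

#' Full pre-processing chain for one recording
#'
#' Runs band-pass -> notch -> epoch -> per-trial detrend -> artifact
#' rejection, producing the cleaned per-trial signal that the spectral
#' stage consumes.
#'
#' @param rec An [eeg_recording()].
#' @param onsets Trial onsets in seconds; `NULL` segments the recording
#'   into consecutive non-overlapping pseudo-trials (basal use).
#' @param duration_s Trial duration in seconds.
#' @param condition,hand Passed to [epoch()].
#' @param cfg A [preprocess_config()].
#' @return List with `trials` (clean [trial_set()]), `rejected_indices`
#'   and `n_kept`.
#' @export
preprocess_recording <- function(rec, onsets = NULL, duration_s = 2,
                                 condition = c("basal", "motor"),
                                 hand = c("none", "right", "left"),
                                 cfg = preprocess_config()) {
  condition <- match.arg(condition)
  hand <- match.arg(hand)
  filtered <- eeg_recording(bandpass_notch(rec$samples, rec$fs, cfg),
                            rec$fs, rec$channel_label, rec$annotations)
  ts <- if (is.null(onsets)) {
    epoch_basal(filtered, duration_s)
  } else {
    epoch(filtered, onsets, duration_s, condition, hand)
  }
  if (cfg$detrend) ts$trials <- lapply(ts$trials, detrend_linear)
  res <- reject_artifacts(ts, cfg)
  list(trials = res$trials, rejected_indices = res$rejected_indices,
       n_kept = length(res$trials$trials))
}
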