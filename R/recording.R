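#' Single-channel EEG recording
#'
#' Container for one channel of sampled EEG: a voltage trace in microvolts,
#' its sampling frequency, a channel label and optional event annotations
#' (cue markers). All downstream functions in the package operate on this
#' representation regardless of whether the data came from an EDF file or
#' from the synthetic generator.
#'
#' @param samples Numeric vector of voltages in microvolts; must be
#'   non-empty and finite.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param channel_label Channel name, e.g. `"Cz"`.
#' @param annotations Data frame with columns `onset` (seconds from start
#'   of recording) and `label` (character), or `NULL` for none. Onsets must
#'   lie within `[0, duration)`.
#'
#' @return An object of class `eeg_recording` with elements `samples`,
#'   `fs`, `channel_label`, `annotations`.
#' @export
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * (0:2047) / 2048), fs = 2048)
#' duration(rec)
eeg_recording <- function(samples, fs, channel_label = "Cz",
                          annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("'samples' must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive scalar (Hz)", call. = FALSE)
  if (is.null(annotations)) {
    annotations <- data.frame(onset = numeric(0), label = character(0),
                              stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (!all(c("onset", "label") %in% names(annotations)))
      stop("'annotations' needs columns 'onset' and 'label'", call. = FALSE)
    annotations$onset <- as.numeric(annotations$onset)
    annotations$label <- as.character(annotations$label)
    dur <- length(samples) / fs
    if (any(annotations$onset < 0 | annotations$onset >= dur))
      stop("annotation onsets must lie within [0, duration)", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs,
                 channel_label = as.character(channel_label)[1L],
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> channel %s: %d samples @ %g Hz (%.3f s), %d annotation(s)\n",
              x$channel_label, length(x$samples), x$fs,
              length(x$samples) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$fs
}

#' Set of equal-length trials
#'
#' An ordered collection of equal-length voltage segments cut from a
#' recording, tagged with the experimental condition. Basal (resting)
#' recordings carry `hand = "none"`.
#'
#' @param trials List of numeric vectors (microvolts), all the same length.
#' @param fs Sampling frequency in Hz.
#' @param condition `"basal"` or `"motor"`.
#' @param hand `"right"`, `"left"` or `"none"`. Basal implies `"none"`.
#' @param trial_duration_s Trial duration in seconds; every trial must hold
#'   exactly `round(trial_duration_s * fs)` samples.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, fs, condition = c("basal", "motor"),
                      hand = c("none", "right", "left"),
                      trial_duration_s) {
  condition <- match.arg(condition)
  hand <- match.arg(hand)
  if (condition == "basal" && hand != "none")
    stop("basal condition implies hand = 'none'", call. = FALSE)
  if (!is.list(trials)) trials <- as.list(as.data.frame(trials))
  n_expect <- round(trial_duration_s * fs)
  lens <- vapply(trials, length, integer(1))
  if (length(trials) > 0L && !all(lens == n_expect))
    stop(sprintf("every trial must have exactly %d samples", n_expect),
         call. = FALSE)
  structure(list(trials = trials, fs = fs, condition = condition,
                 hand = hand, trial_duration_s = trial_duration_s),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d %s trial(s) (hand: %s) of %g s @ %g Hz\n",
              length(x$trials), x$condition, x$hand,
              x$trial_duration_s, x$fs))
  invisible(x)
}

#' Number of trials
#' @param x A [trial_set()].
#' @param ... Unused.
#' @export
length.trial_set <- function(x) length(x$trials)

#' Cut a recording into trials
#'
#' Extracts one segment per onset using the half-open window
#' `[onset, onset + duration_s)`; the first sample index is
#' `floor(onset * fs)`, so trials are causal with respect to the cue.
#'
#' @param rec An [eeg_recording()].
#' @param onsets Numeric vector of onset times in seconds. May be empty.
#' @param duration_s Trial duration in seconds.
#' @inheritParams trial_set
#' @return A [trial_set()] with one trial per onset, in onset order.
#' @export
#' @examples
#' rec <- eeg_recording(rnorm(2048 * 10), fs = 2048)
#' ts <- epoch(rec, onsets = c(0, 2, 4), duration_s = 2,
#'             condition = "motor", hand = "right")
#' length(ts)
epoch <- function(rec, onsets, duration_s,
                  condition = c("basal", "motor"),
                  hand = c("none", "right", "left")) {
  stopifnot(inherits(rec, "eeg_recording"))
  condition <- match.arg(condition)
  hand <- match.arg(hand)
  n <- round(duration_s * rec$fs)
  dur <- duration(rec)
  if (length(onsets) > 0L && any(onsets < 0 | onsets + duration_s > dur + 1e-9))
    stop("onset + duration exceeds the recording", call. = FALSE)
  trials <- lapply(onsets, function(t0) {
    i0 <- floor(t0 * rec$fs) + 1L
    rec$samples[i0:(i0 + n - 1L)]
  })
  trial_set(trials, rec$fs, condition, hand, duration_s)
}

#' Cut a basal recording into consecutive pseudo-trials
#'
#' A resting recording has no cues; to give basal and motor band-power
#' estimates matched spectral resolution it is segmented into consecutive
#' non-overlapping pseudo-trials of the same duration as the motor trials.
#'
#' @inheritParams epoch
#' @return A [trial_set()] with `condition = "basal"`.
#' @export
epoch_basal <- function(rec, duration_s) {
  k <- floor(duration(rec) / duration_s)
  if (k < 1L) stop("recording shorter than one trial", call. = FALSE)
  epoch(rec, onsets = (seq_len(k) - 1L) * duration_s, duration_s,
        condition = "basal", hand = "none")
}
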