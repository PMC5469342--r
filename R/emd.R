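# Empirical Mode Decomposition by cubic-spline envelope sifting.
#
# EMD writes a signal as a finite sum of intrinsic mode functions (IMFs)
# plus a residue: x(t) = sum_j IMF_j(t) + r_N(t). Each IMF is extracted by
# "sifting": (i) locate all local extrema, (ii) interpolate maxima and
# minima separately with natural cubic splines to get upper/lower
# envelopes, (iii) form the envelope mean M(t) = (UE + LE)/2, (iv)
# subtract, c(t) = x(t) - M(t); repeat on c(t) until it qualifies as an
# IMF. The IMF is removed and sifting restarts on the residue, estimating
# the highest-frequency mode first. The reconstruction identity holds
# exactly by construction, whatever the stopping rules do.

#' EMD configuration
#'
#' @param max_imfs Maximum number of IMFs to extract (default 5; the
#'   decomposition stops there even if the residue still oscillates).
#' @param sift_sd_threshold Cauchy-type sifting convergence bound: sifting
#'   of one IMF stops when
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` falls below it (default 0.2,
#'   the conventional value).
#' @param max_sifts_per_imf Hard cap on sifting iterations per IMF.
#' @param residue_energy_frac Stop when the extracted component's (or the
#'   residue's) energy falls below this fraction of the input energy —
#'   the "too small to matter" rule.
#' @param boundary Envelope end-condition strategy; `"mirror"` reflects
#'   the two extrema nearest each end across the end sample before spline
#'   fitting, which suppresses spline flare-out at the edges.
#' @return An `emd_config` list.
#' @export
emd_config <- function(max_imfs = 5L, sift_sd_threshold = 0.2,
                       max_sifts_per_imf = 50L,
                       residue_energy_frac = 1e-6,
                       boundary = c("mirror", "none")) {
  boundary <- match.arg(boundary)
  stopifnot(max_imfs >= 1, sift_sd_threshold > 0,
            max_sifts_per_imf >= 1, residue_energy_frac > 0)
  structure(list(max_imfs = as.integer(max_imfs),
                 sift_sd_threshold = sift_sd_threshold,
                 max_sifts_per_imf = as.integer(max_sifts_per_imf),
                 residue_energy_frac = residue_energy_frac,
                 boundary = boundary),
            class = "emd_config")
}

#' Locate local extrema
#'
#' Strict local maxima and minima by sign change of the first difference.
#' A plateau (run of equal samples between opposite slopes) contributes
#' its midpoint index. Endpoints are never reported as interior extrema.
#'
#' @param x Numeric series, length >= 3.
#' @return List with integer vectors `maxima` and `minima` (1-based).
#' @export
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0))  # maxima 2, minima 4
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2)
    return(list(maxima = integer(0), minima = integer(0)))
  sv <- s[nz]
  chg <- which(sv[-length(sv)] != sv[-1])   # slope sign flips
  if (length(chg) == 0)
    return(list(maxima = integer(0), minima = integer(0)))
  # plateau spans samples (nz[k]+1) .. nz[k+1]; midpoint breaks ties
  idx <- (nz[chg] + 1L + nz[chg + 1L]) %/% 2L
  is_max <- sv[chg] > 0
  list(maxima = idx[is_max], minima = idx[!is_max])
}

#' Spline envelope through extrema
#'
#' Natural cubic spline through the samples at `extrema_idx`, evaluated at
#' every sample position. With `boundary = "mirror"` the two extrema
#' nearest each end are reflected across the end sample first, anchoring
#' the spline outside the data span.
#'
#' @param x Numeric series.
#' @param extrema_idx Indices of the extrema of one kind (maxima or
#'   minima); at least 2 required.
#' @param boundary `"mirror"` or `"none"`.
#' @return Numeric envelope, same length as `x`.
#' @export
emd_envelope <- function(x, extrema_idx, boundary = "mirror") {
  n <- length(x)
  k <- length(extrema_idx)
  if (k < 1 || (k < 2 && boundary == "none"))
    stop("need at least 2 extrema for an envelope (monotone residue)",
         call. = FALSE)
  t <- as.numeric(extrema_idx)
  v <- x[extrema_idx]
  if (boundary == "mirror") {
    nl <- min(2L, k)
    left_t <- 2 - rev(t[seq_len(nl)])
    left_v <- rev(v[seq_len(nl)])
    right_t <- 2 * n - rev(t[(k - nl + 1L):k])
    right_v <- rev(v[(k - nl + 1L):k])
    t <- c(left_t, t, right_t)
    v <- c(left_v, v, right_v)
    keep <- !duplicated(t)
    t <- t[keep]; v <- v[keep]
    o <- order(t); t <- t[o]; v <- v[o]
  }
  if (length(t) == 2) {         # spline degenerates to the straight line
    return(v[1] + (v[2] - v[1]) * (seq_len(n) - t[1]) / (t[2] - t[1]))
  }
  stats::spline(t, v, xout = seq_len(n), method = "natural")$y
}

# count zero crossings (sign changes, exact zeros collapsed)
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-length(s)] != s[-1])
}

# IMF count criterion away from the ends: extrema and zero crossings of
# the interior (two boundary samples excluded at each end, where the
# mirror extension dominates) must agree to within `tol`
imf_counts_interior <- function(x, tol = 1L, exclude = 2L) {
  n <- length(x)
  if (n <= 2 * exclude + 2) return(FALSE)
  core <- x[(exclude + 1L):(n - exclude)]
  ex <- find_extrema(core)
  abs(length(ex$maxima) + length(ex$minima) -
        count_zero_crossings(core)) <= tol
}

#' Test the intrinsic-mode-function criteria
#'
#' A series qualifies as an IMF when (1) its numbers of extrema and of
#' zero crossings differ by at most `tolerance_extrema_diff`, and (2) the
#' mean of its spline envelopes is close to zero everywhere, measured as
#' envelope-mean RMS below `sd_threshold` times the RMS of the series.
#'
#' @param c Numeric series, length >= 3.
#' @param tolerance_extrema_diff Allowed extrema/zero-crossing mismatch
#'   (default 1).
#' @param sd_threshold Envelope-mean RMS bound relative to signal RMS.
#' @param boundary Envelope boundary strategy, see [emd_envelope()].
#' @return `TRUE` or `FALSE`.
#' @export
is_imf <- function(c, tolerance_extrema_diff = 1L, sd_threshold = 0.2,
                   boundary = "mirror") {
  n <- length(c)
  if (n < 3) return(FALSE)
  ex <- find_extrema(c)
  n_ext <- length(ex$maxima) + length(ex$minima)
  if (length(ex$maxima) < 1 || length(ex$minima) < 1) return(FALSE)
  if (abs(n_ext - count_zero_crossings(c)) > tolerance_extrema_diff)
    return(FALSE)
  ue <- emd_envelope(c, ex$maxima, boundary)
  le <- emd_envelope(c, ex$minima, boundary)
  m <- (ue + le) / 2
  sqrt(mean(m^2)) < sd_threshold * sqrt(mean(c^2))
}

#' Empirical Mode Decomposition
#'
#' Decomposes a series into intrinsic mode functions and a residue by
#' envelope sifting. Sifting of each IMF iterates extrema detection,
#' spline envelopes and envelope-mean subtraction until the Cauchy
#' criterion falls below `sift_sd_threshold` (or `max_sifts_per_imf` is
#' hit). The outer loop stops when (1) the residue has at most one
#' extremum, (2) the extracted component or residue energy is negligible
#' (`residue_energy_frac` of the input energy), or (3) `max_imfs` IMFs
#' have been extracted. The sum of all IMFs plus the residue reproduces
#' the input to machine precision.
#'
#' @param x Numeric series (finite, length >= 8).
#' @param cfg An [emd_config()].
#' @param fs Sampling frequency in Hz (carried for diagnostics; the
#'   decomposition itself is sample-based).
#' @return An object of class `imf_decomposition`: list with `imfs` (list
#'   of series, highest frequency first), `residue`, `n_imfs`, `fs`.
#' @export
#' @examples
#' t <- (0:4095) / 2048
#' x <- sin(2 * pi * 40 * t) + sin(2 * pi * 4 * t)
#' d <- emd(x, fs = 2048)
#' d$n_imfs
emd <- function(x, cfg = emd_config(), fs = NA_real_) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  if (length(x) < 8) stop("input too short for EMD", call. = FALSE)
  e_in <- sum(x^2)
  residue <- x
  imfs <- list()
  repeat {
    if (length(imfs) >= cfg$max_imfs) break
    ex <- find_extrema(residue)
    if (length(ex$maxima) + length(ex$minima) <= 1) break
    if (length(ex$maxima) < 1 || length(ex$minima) < 1) break
    h <- residue
    for (it in seq_len(cfg$max_sifts_per_imf)) {
      exh <- find_extrema(h)
      if (length(exh$maxima) < 1 || length(exh$minima) < 1) break
      ue <- emd_envelope(h, exh$maxima, cfg$boundary)
      le <- emd_envelope(h, exh$minima, cfg$boundary)
      m <- (ue + le) / 2
      h_new <- h - m
      sd <- sum(m^2) / sum(h^2)
      h <- h_new
      # a candidate is accepted once the envelope-mean correction is
      # negligible AND the extrema/zero-crossing counts agree
      if (sd < cfg$sift_sd_threshold && imf_counts_interior(h)) break
    }
    if (e_in > 0 && sum(h^2) < cfg$residue_energy_frac * e_in) break
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
    if (e_in > 0 && sum(residue^2) < cfg$residue_energy_frac * e_in) break
  }
  structure(list(imfs = imfs, residue = residue,
                 n_imfs = length(imfs), fs = fs),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMF(s) + residue, %d samples\n",
              x$n_imfs, length(x$residue)))
  if (x$n_imfs > 0 && is.finite(x$fs)) {
    mf <- vapply(x$imfs, mean_frequency, numeric(1), fs = x$fs)
    cat("  mean frequencies (Hz):", paste(round(mf, 1), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Check the sampling-rate condition for a band of interest
#'
#' EMD separates a component cleanly only when the sampling rate is about
#' five times the highest frequency of interest; warn when it is not.
#'
#' @param fs Sampling frequency in Hz.
#' @param f_max Highest frequency of interest in Hz.
#' @return `TRUE` (invisibly) if the condition holds, otherwise `FALSE`
#'   with a warning.
#' @export
check_emd_sampling <- function(fs, f_max) {
  ok <- fs >= 5 * f_max
  if (!ok)
    warning(sprintf(paste0("sampling rate %g Hz is below 5x the highest ",
                           "frequency of interest (%g Hz); EMD band ",
                           "separation may be unreliable"), fs, f_max),
            call. = FALSE)
  invisible(ok)
}

#' Power-weighted mean frequency
#'
#' Mean of the periodogram frequency axis weighted by power, after mean
#' removal (DC excluded). Used to verify that IMFs come out in decreasing
#' frequency order.
#'
#' @param imf Numeric series.
#' @param fs Sampling frequency in Hz.
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(imf, fs) {
  x <- imf - mean(imf)
  if (all(x == 0)) stop("degenerate (all-zero) series", call. = FALSE)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  nb <- floor(n / 2) + 1L
  p <- p[seq_len(nb)]
  f <- (seq_len(nb) - 1) * fs / n
  sum(f * p) / sum(p)
}
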